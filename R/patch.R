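# Patch extraction: minimum-variance two-cluster split of centrality
# scores, connected-component extraction, conservation metrics with a
# one-sided Mann-Whitney test, and the iterative multi-patch loop.

#' Two-cluster minimum-variance split of centrality scores
#'
#' Partitions one-dimensional scores into a high and a low cluster by the
#' threshold split minimising the total within-cluster sum of squares --
#' the exact optimum of minimum-variance (Ward-style) hierarchical
#' clustering cut at two clusters for 1-D data. Equal scores always land
#' in the same cluster; the high cluster is the one containing the maximum
#' score.
#'
#' @param scores Named numeric vector (e.g. centrality per residue).
#' @return List with `high` and `low` (character vectors of names) and
#'   `threshold` (scores strictly above it are high).
#' @export
split_clusters <- function(scores) {
  if (length(scores) < 2 || length(unique(scores)) < 2)
    stop2("all scores identical; two-cluster split is undefined",
          class = "sp_degenerate_split_error")
  nm <- names(scores) %||% as.character(seq_along(scores))
  v <- sort(unique(scores))
  s <- sort(scores)
  n <- length(s)
  cs <- cumsum(s); cs2 <- cumsum(s^2)
  # candidate cuts between consecutive distinct values
  cut_at <- match(v[-length(v)], s) + (tabulate(match(s, v))[-length(v)]) - 1L
  within <- vapply(cut_at, function(k) {
    lowss <- cs2[k] - cs[k]^2 / k
    hi_n <- n - k
    hiss <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / hi_n
    lowss + hiss
  }, numeric(1))
  best <- which.min(within)
  thr <- (v[best] + v[best + 1]) / 2
  list(high = nm[scores > thr], low = nm[scores <= thr], threshold = thr)
}

#' Extract the connected high-centrality patch
#'
#' Within the subgraph induced by the high cluster (edges taken as
#' undirected), returns the connected component containing the
#' highest-centrality node (ties broken by the lowest residue index).
#' High-cluster members unreachable from that seed are excluded, so the
#' patch is always a connected accessible surface.
#'
#' @param graph TAC graph.
#' @param scores Named centrality scores.
#' @param high Character vector of high-cluster node names.
#' @return Character vector of patch node names, with the seed node in
#'   attribute `"seed"`.
#' @export
extract_patch <- function(graph, scores, high) {
  if (!length(high)) stop2("empty high cluster", class = "sp_input_error")
  hs <- scores[high]
  seed <- high[hs == max(hs)]
  seed <- seed[order(as.numeric(seed))][1]
  sub <- igraph::induced_subgraph(graph, vids = high)
  und <- igraph::as_undirected(sub, mode = "collapse")
  comp <- igraph::components(und)
  memb <- comp$membership[seed]
  patch <- names(comp$membership)[comp$membership == memb]
  attr(patch, "seed") <- seed
  patch
}

#' One-sided Mann-Whitney U test (greater)
#'
#' Tests whether the distribution underlying `x` is stochastically greater
#' than that underlying `y`. For small samples (`min(n, m) <= 8` and
#' `max(n, m) <= 25`) the p-value is exact, enumerating every assignment of
#' the pooled midranks; otherwise the normal approximation with tie
#' correction and continuity correction is used. Ties are handled by
#' midranks in both branches, so complete degeneracy (all values equal)
#' yields p = 1 under the exact test.
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (U for x), `p_value` and `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney_greater <- function(x, y) {
  n <- length(x); m <- length(y)
  if (!n || !m) stop2("both samples must be nonempty", class = "sp_input_error")
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  k <- min(n, m)
  exact_ok <- k <= 8 && max(n, m) <= 25 && choose(n + m, k) <= 5e5
  if (exact_ok) {
    combos <- utils::combn(n + m, k)
    Uk <- colSums(matrix(r[combos], nrow = k)) - k * (k + 1) / 2
    # U_x + U_y = n*m holds with midranks, so enumerate the smaller group
    Us <- if (k == n) Uk else n * m - Uk
    p <- mean(Us >= U - 1e-9)
    list(statistic = U, p_value = p, method = "exact")
  } else {
    N <- n + m
    mu <- n * m / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(statistic = U, p_value = 1, method = "normal"))
    z <- (U - mu - 0.5) / sqrt(sigma2)
    list(statistic = U, p_value = stats::pnorm(z, lower.tail = FALSE),
         method = "normal")
  }
}

#' Conservation metrics of a patch
#'
#' Computes (i) absolute patch conservation, the mean WCS over the patch;
#' (ii) relative patch conservation, the difference between the patch mean
#' and the mean over the non-patch surface residues; and (iii) the
#' associated one-sided Mann-Whitney p-value for the alternative that
#' patch conservation is stochastically greater than non-patch surface
#' conservation.
#'
#' @param patch Character (or integer) vector of patch residue indices.
#' @param conservation Named numeric vector of WCS over the surface
#'   residues under consideration (patch plus non-patch).
#' @return List `absolute`, `relative`, `p_value`, `method`.
#' @export
score_patch <- function(patch, conservation) {
  patch <- as.character(patch)
  rest <- setdiff(names(conservation), patch)
  if (!length(rest))
    stop2("non-patch surface is empty; relative conservation undefined",
          class = "sp_scoring_error")
  xs <- unname(conservation[patch])
  ys <- unname(conservation[rest])
  mw <- mann_whitney_greater(xs, ys)
  list(absolute = mean(xs),
       relative = mean(xs) - mean(ys),
       p_value = mw$p_value,
       method = mw$method)
}

#' Iterative extraction of multiple conserved patches
#'
#' Runs the centrality / split / extract / score cycle, removes the patch
#' residues from the TAC graph, recomputes the incoming-edge weights (the
#' indegrees change) and the centrality on the reduced graph, and repeats.
#' The loop stops at `max_patches`, when the reduced graph runs out of
#' edges or of score variation, or when a patch's relative-conservation
#' p-value exceeds `p_cutoff` (that patch is still reported, flagged
#' non-significant).
#'
#' @param graph TAC graph of one structural module.
#' @param max_patches Iteration cap. Default 3.
#' @param p_cutoff Significance cut-off halting the iteration. Default
#'   `1e-10`, the proteome-scale filter value; set to 1 to disable.
#' @param tol,max_iter Passed to [eigenvector_centrality()].
#' @return List of `conserved_patch` objects: fields `iteration`,
#'   `residues`, `seed`, `absolute`, `relative`, `p_value`, `significant`,
#'   `centrality` (scores on the graph the patch was extracted from).
#' @export
iterate_patches <- function(graph, max_patches = 3, p_cutoff = 1e-10,
                            tol = 1e-8, max_iter = 1000) {
  out <- list()
  g <- graph
  for (it in seq_len(max_patches)) {
    if (igraph::vcount(g) < 2 || igraph::ecount(g) == 0) break
    cent <- tryCatch(eigenvector_centrality(g, tol = tol, max_iter = max_iter),
                     surfpatch_error = function(e) NULL)
    if (is.null(cent)) break
    sp <- tryCatch(split_clusters(cent),
                   sp_degenerate_split_error = function(e) NULL)
    if (is.null(sp)) break
    patch <- extract_patch(g, cent, sp$high)
    cons <- stats::setNames(igraph::V(g)$conservation, igraph::V(g)$name)
    sc <- tryCatch(score_patch(patch, cons),
                   sp_scoring_error = function(e) NULL)
    if (is.null(sc)) break
    rec <- structure(list(
      iteration = it,
      residues = sort(as.integer(patch)),
      seed = as.integer(attr(patch, "seed")),
      absolute = sc$absolute,
      relative = sc$relative,
      p_value = sc$p_value,
      significant = sc$p_value <= p_cutoff,
      centrality = cent
    ), class = "conserved_patch")
    out[[length(out) + 1L]] <- rec
    if (!rec$significant) break
    keep <- setdiff(igraph::V(g)$name, patch)
    if (length(keep) < 2) break
    g <- rebuild_tac_weights(igraph::induced_subgraph(g, vids = keep))
  }
  out
}

# after node removal the indegrees change; recompute w(u->v) = c(v)/indeg(v)
rebuild_tac_weights <- function(g) {
  if (!igraph::ecount(g)) return(g)
  indeg <- igraph::degree(g, mode = "in")
  head <- igraph::head_of(g, igraph::E(g))
  cons <- igraph::V(g)$conservation
  igraph::E(g)$weight <- cons[head] / indeg[head]
  g
}

#' @export
print.conserved_patch <- function(x, ...) {
  cat(sprintf("<conserved_patch> iteration %d: %d residues (seed %d), absolute %.3f, relative %.3f, p = %.3g%s\n",
              x$iteration, length(x$residues), x$seed, x$absolute, x$relative,
              x$p_value, if (x$significant) "" else " (not significant)"))
  invisible(x)
}
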