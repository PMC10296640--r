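# Autonomous structural module definition: community detection on the
# inverse-PAE residue graph of a predicted model.

#' Build the inverse-PAE residue graph
#'
#' Nodes are residues whose predicted confidence (pLDDT) exceeds
#' `plddt_min`; an undirected edge joins residues i and j when the
#' symmetrised predicted aligned error (arithmetic mean of the two matrix
#' directions) is strictly below `pae_max` Angstrom. Edge weights are the
#' inverse of the symmetrised PAE, with the PAE floored at `pae_floor`
#' before inversion so near-zero entries cannot dominate.
#'
#' @param structure A `protein_structure` with pLDDT (predicted model).
#' @param pae An n x n PAE matrix matching the residue count.
#' @param plddt_min Confidence threshold; residues must satisfy
#'   `plddt > plddt_min` (strict). Default 70.
#' @param pae_max Edge threshold in Angstrom, strict (`PAE < pae_max`).
#'   Default 5.
#' @param pae_floor Lower clamp in Angstrom applied before inversion.
#'   Default 0.2.
#' @return An [igraph::graph] with vertex names equal to residue sequence
#'   indices and edge attribute `weight` in 1/Angstrom.
#' @export
build_pae_graph <- function(structure, pae, plddt_min = 70, pae_max = 5,
                            pae_floor = 0.2) {
  res <- structure$residues
  n <- nrow(res)
  if (!is.matrix(pae) || nrow(pae) != n || ncol(pae) != n)
    stop2("PAE dimension (", nrow(pae), ") does not match residue count (",
          n, ")", class = "sp_dimension_error")
  if (anyNA(res$plddt))
    stop2("structure has no per-residue pLDDT; module segmentation needs a ",
          "predicted model", class = "sp_input_error")
  keep <- which(res$plddt > plddt_min)
  sym <- (pae + t(pae)) / 2
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  igraph::V(g)$name <- as.character(res$seq_index[keep])
  if (length(keep) >= 2) {
    sub <- sym[keep, keep, drop = FALSE]
    idx <- which(upper.tri(sub) & sub < pae_max, arr.ind = TRUE)
    if (nrow(idx)) {
      w <- 1 / pmax(sub[idx], pae_floor)
      g <- igraph::add_edges(g, rbind(idx[, 1], idx[, 2]), weight = w)
    }
  }
  g
}

#' Greedy modularity community detection with a resolution parameter
#'
#' Agglomerative modularity maximisation: every node starts as its own
#' community and the pair of communities whose merge yields the largest
#' modularity gain is merged repeatedly, while a strictly positive gain
#' exists. The resolution parameter scales the null-model term of
#' modularity: at resolution zero only intra-community edge weight counts,
#' so any connected graph collapses to one community per component; larger
#' resolutions favour smaller communities. Ties in the gain are broken by
#' the lexicographically smallest pair of community labels (a community is
#' labelled by its smallest member node), making the partition
#' deterministic.
#'
#' @param graph Undirected weighted [igraph::graph].
#' @param resolution Non-negative resolution parameter (dimensionless).
#' @return A named integer vector: community id (1-based, arbitrary order)
#'   per vertex name.
#' @export
detect_communities <- function(graph, resolution = 1) {
  nv <- igraph::vcount(graph)
  if (nv == 0) stop2("empty graph", class = "sp_input_error")
  nm <- igraph::V(graph)$name %||% as.character(seq_len(nv))
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- igraph::E(graph)$weight %||% rep(1, nrow(el))
  memb <- seq_len(nv)
  if (nrow(el) == 0 || sum(w) <= 0)
    return(stats::setNames(memb, nm))

  m2 <- 2 * sum(w)
  # community-level aggregates
  E <- matrix(0, nv, nv)  # inter-community weight (symmetric, zero diag)
  for (k in seq_len(nrow(el))) {
    i <- el[k, 1]; j <- el[k, 2]
    if (i != j) { E[i, j] <- E[i, j] + w[k]; E[j, i] <- E[j, i] + w[k] }
  }
  A <- rowSums(E) / m2  # fraction of total degree per community
  label <- seq_len(nv)          # smallest member node id per community
  alive <- rep(TRUE, nv)

  repeat {
    # gain of merging a,b: 2 * (E_ab/m2 - resolution * A_a * A_b)
    gain <- 2 * (E / m2 - resolution * outer(A, A))
    gain[!alive, ] <- -Inf; gain[, !alive] <- -Inf
    diag(gain) <- -Inf
    best <- max(gain)
    if (!is.finite(best) || best <= 1e-15) break
    cand <- which(gain >= best - 1e-12 & is.finite(gain), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    lb <- cbind(label[cand[, 1]], label[cand[, 2]])
    lb <- t(apply(lb, 1, sort))
    pick <- order(lb[, 1], lb[, 2])[1]
    a <- cand[pick, 1]; b <- cand[pick, 2]
    # merge b into a
    memb[memb == b] <- a
    E[a, ] <- E[a, ] + E[b, ]
    E[, a] <- E[, a] + E[, b]
    E[a, a] <- 0
    E[b, ] <- 0; E[, b] <- 0
    A[a] <- A[a] + A[b]; A[b] <- 0
    label[a] <- min(label[a], label[b])
    alive[b] <- FALSE
  }
  comm <- match(memb, sort(unique(memb)))
  stats::setNames(comm, nm)
}

#' Modularity of a partition at a given resolution
#'
#' @param graph Undirected weighted graph.
#' @param membership Integer community id per vertex (in vertex order).
#' @param resolution Resolution parameter.
#' @return Scalar modularity.
#' @export
partition_modularity <- function(graph, membership, resolution = 1) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- igraph::E(graph)$weight %||% rep(1, nrow(el))
  m2 <- 2 * sum(w)
  if (m2 <= 0) return(0)
  deg <- numeric(igraph::vcount(graph))
  for (k in seq_len(nrow(el))) {
    deg[el[k, 1]] <- deg[el[k, 1]] + w[k]
    deg[el[k, 2]] <- deg[el[k, 2]] + w[k]
  }
  same <- membership[el[, 1]] == membership[el[, 2]]
  intra <- sum(w[same]) * 2 / m2
  null <- sum(tapply(deg, membership, sum)^2) / m2^2
  intra - resolution * null
}

#' Filter communities into structural modules
#'
#' Communities smaller than `min_size` residues (the lower bound for a
#' stably folded domain) are excluded; survivors are annotated with their
#' mean intra-module symmetrised PAE and mean pLDDT and ranked by size.
#'
#' @param partition Named membership vector from [detect_communities()].
#' @param structure The `protein_structure` the partition refers to.
#' @param pae The PAE matrix.
#' @param min_size Minimum residue count (strictly-less-than excluded).
#'   Default 30.
#' @return A list of `structural_module` objects (fields `residues`,
#'   `mean_pae`, `mean_plddt`, `rank`), largest first. Empty list if every
#'   community was filtered.
#' @export
filter_modules <- function(partition, structure, pae, min_size = 30) {
  if (!length(partition)) return(list())
  sym <- (pae + t(pae)) / 2
  res <- structure$residues
  groups <- split(as.integer(names(partition)), partition)
  groups <- groups[lengths(groups) >= min_size]
  if (!length(groups)) {
    sp_log("all communities below ", min_size, " residues; no modules")
    return(list())
  }
  groups <- groups[order(-lengths(groups))]
  out <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    ridx <- sort(groups[[k]])
    rows <- match(ridx, res$seq_index)
    block <- sym[rows, rows, drop = FALSE]
    mp <- mean(block[upper.tri(block)])
    out[[k]] <- structure(list(
      residues = ridx,
      mean_pae = mp,
      mean_plddt = mean(res$plddt[rows]),
      rank = k
    ), class = "structural_module")
  }
  out
}

#' @export
print.structural_module <- function(x, ...) {
  cat("<structural_module> rank ", x$rank, ": ", length(x$residues),
      " residues, mean PAE ", round(x$mean_pae, 2), " A, mean pLDDT ",
      round(x$mean_plddt, 1), "\n", sep = "")
  invisible(x)
}

#' Calibrate the community-detection resolution on annotated domains
#'
#' Scans the resolution downward from 1 to 0 in steps of 0.01 and returns
#' the highest value at which no reference domain in the calibration
#' collection is split across two communities. This keeps modules as small
#' as possible subject to never cutting a known domain in half.
#'
#' @param structures List of `protein_structure` objects.
#' @param paes List of matching PAE matrices.
#' @param domain_annotations List (per protein) of two-column matrices or
#'   data frames of residue ranges `(start, end)` for reference domains.
#' @param plddt_min,pae_max Graph thresholds, as in [build_pae_graph()].
#' @param step Scan step. Default 0.01.
#' @return The selected resolution (0 with a warning if no value keeps all
#'   domains intact).
#' @export
optimize_resolution <- function(structures, paes, domain_annotations,
                                plddt_min = 70, pae_max = 5, step = 0.01) {
  if (!length(structures)) stop2("empty calibration collection",
                                 class = "sp_input_error")
  graphs <- Map(function(s, p) build_pae_graph(s, p, plddt_min, pae_max),
                structures, paes)
  for (r in rev(seq(0, 1, by = step))) {
    ok <- TRUE
    for (i in seq_along(graphs)) {
      part <- detect_communities(graphs[[i]], resolution = r)
      doms <- domain_annotations[[i]]
      for (d in seq_len(nrow(doms))) {
        span <- seq(doms[d, 1], doms[d, 2])
        ids <- part[as.character(span)]
        ids <- ids[!is.na(ids)]
        if (length(unique(ids)) > 1) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) return(r)
  }
  warning("no resolution in [0, 1] keeps all reference domains intact; returning 0")
  0
}
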