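# The topology-accessibility-conservation (TAC) graph and its eigenvector
# centrality.

#' Build the TAC graph of a structural module
#'
#' Directed graph over the accessible residues of a structural module. Each
#' unordered Delaunay adjacency pair contributes both directed edges, and
#' every incoming edge of a node carries that node's conservation score
#' divided by its indegree, so the incoming weights of a connected node sum
#' exactly to its conservation. A node with conservation 0.5 and five
#' neighbours therefore receives five incoming edges of weight 0.5/5 each.
#' Isolated accessible residues are kept as isolated nodes.
#'
#' @param accessible Integer vector of accessible residue sequence indices.
#' @param adjacency Two-column matrix of unordered residue pairs (subset of
#'   `accessible`), as from [residue_adjacency()].
#' @param conservation Named numeric vector (per residue sequence index) of
#'   conservation scores in \[0, 1\].
#' @return A directed weighted [igraph::graph] with vertex attribute
#'   `conservation` and edge attribute `weight`.
#' @export
build_tac_graph <- function(accessible, adjacency, conservation) {
  if (!length(accessible))
    stop2("no accessible residues; TAC graph is empty", class = "sp_empty_graph_error")
  nm <- as.character(sort(accessible))
  cons <- conservation[nm]
  if (anyNA(cons))
    stop2("conservation missing for residues: ",
          paste(nm[is.na(cons)], collapse = ", "), class = "sp_input_error")
  g <- igraph::make_empty_graph(n = length(nm), directed = TRUE)
  igraph::V(g)$name <- nm
  igraph::V(g)$conservation <- unname(cons)
  if (!is.null(adjacency) && nrow(adjacency)) {
    bad <- !(adjacency[, 1] %in% accessible & adjacency[, 2] %in% accessible)
    if (any(bad))
      stop2("adjacency refers to non-accessible residues", class = "sp_input_error")
    a <- as.character(adjacency[, 1]); b <- as.character(adjacency[, 2])
    indeg <- table(c(a, b))  # symmetric relation: indegree == degree
    from <- c(a, b); to <- c(b, a)
    w <- unname(cons[to] / as.numeric(indeg[to]))
    g <- igraph::add_edges(g, rbind(match(from, nm), match(to, nm)), weight = w)
  }
  niso <- sum(igraph::degree(g) == 0)
  if (niso) sp_log(niso, " isolated accessible residue(s) in TAC graph")
  g
}

#' Eigenvector centrality of a TAC graph
#'
#' Power iteration for the dominant eigenvector of the incoming-edge
#' weighted adjacency operator: a node's score accumulates the scores of
#' its in-neighbours, scaled by the incoming edge weights, so residues
#' embedded in conserved neighbourhoods rise above isolated conserved
#' residues. The iteration starts from the uniform vector and applies the
#' shifted update `x <- x + W'x` (identity shift), which converges on
#' reducible non-negative graphs where the pure update can oscillate or
#' vanish; the shift leaves the eigenvectors unchanged. Scores are
#' non-negative and L2-normalised, and the computation is fully
#' deterministic.
#'
#' @param graph TAC graph from [build_tac_graph()].
#' @param tol Convergence tolerance on the L1 change of successive
#'   normalised iterates. Default `1e-8`.
#' @param max_iter Iteration cap; exceeding it is an error carrying the
#'   final residual in its message. Default 1000.
#' @return Named numeric vector of centrality scores (Euclidean norm 1).
#' @export
eigenvector_centrality <- function(graph, tol = 1e-8, max_iter = 1000) {
  n <- igraph::vcount(graph)
  if (n == 0) stop2("empty graph", class = "sp_empty_graph_error")
  nm <- igraph::V(graph)$name
  W <- weight_matrix(graph)
  if (all(W == 0))
    stop2("all TAC edge weights are zero; centrality is degenerate",
          class = "sp_degenerate_graph_error")
  Wt <- t(W)
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    xl <- x
    x <- xl + as.vector(Wt %*% xl)
    nrm <- sqrt(sum(x^2))
    if (nrm == 0)
      stop2("centrality iteration collapsed to zero", class = "sp_degenerate_graph_error")
    x <- x / nrm
    if (sum(abs(x - xl)) < tol)
      return(stats::setNames(x, nm))
  }
  stop2(sprintf("eigenvector centrality did not converge in %d iterations (last L1 change %.3g, tol %.3g)",
                max_iter, sum(abs(x - xl)), tol),
        class = "sp_convergence_error")
}

# dense (from, to) weight matrix in vertex order
weight_matrix <- function(graph) {
  n <- igraph::vcount(graph)
  W <- matrix(0, n, n)
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(el)) W[el] <- igraph::E(graph)$weight
  W
}

#' Export a TAC graph as node-link JSON
#'
#' Serialises nodes (with conservation and optional centrality and
#' accessibility attributes) and directed weighted edges in a node-link
#' shape suitable for visualisation.
#'
#' @param graph TAC graph.
#' @param path Output path.
#' @param centrality Optional named centrality vector to attach.
#' @return `path`, invisibly.
#' @export
write_tac_json <- function(graph, path, centrality = NULL) {
  nm <- igraph::V(graph)$name
  nodes <- data.frame(id = nm,
                      conservation = igraph::V(graph)$conservation,
                      accessible = TRUE)
  if (!is.null(centrality)) nodes$centrality <- unname(centrality[nm])
  el <- igraph::as_edgelist(graph)
  links <- data.frame(source = el[, 1], target = el[, 2],
                      weight = igraph::E(graph)$weight)
  jsonlite::write_json(list(directed = TRUE, nodes = nodes, links = links),
                       path, dataframe = "rows", digits = NA)
  invisible(path)
}
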