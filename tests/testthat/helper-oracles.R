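# Independent oracles and fixture builders shared across the suite.
# Each oracle deliberately uses a different algorithmic route than the
# package implementation it checks.

mini_pdb <- function() system.file("extdata", "mini.pdb", package = "surfpatch")
mini_cif <- function() system.file("extdata", "mini.cif", package = "surfpatch")

# --- geometry ---------------------------------------------------------------

# face multiplicities recomputed with an environment-based counter
bf_surface_atoms <- function(tets) {
  cnt <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(tets))) {
    vs <- tets[i, ]
    for (drop in 1:4) {
      key <- paste(sort(vs[-drop]), collapse = "|")
      cnt[[key]] <- (cnt[[key]] %||% 0L) + 1L
    }
  }
  verts <- integer(0)
  for (key in ls(cnt))
    if (cnt[[key]] == 1L)
      verts <- c(verts, as.integer(strsplit(key, "|", fixed = TRUE)[[1]]))
  sort(unique(verts))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n*m) brute-force interface scan
bf_interface <- function(st, chain_a, chain_b, cutoff) {
  at <- st$atoms
  ra <- st$residues$chain[at$residue] == chain_a
  rb <- st$residues$chain[at$residue] == chain_b
  hits <- integer(0)
  for (i in which(ra)) {
    for (j in which(rb)) {
      d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                (at$z[i] - at$z[j])^2)
      if (d < cutoff) { hits <- c(hits, at$residue[i]); break }
    }
  }
  sort(unique(st$residues$seq_index[hits]))
}

# build a protein_structure from a bare atom table (testing geometry ops
# in isolation, bypassing file parsing)
toy_structure <- function(xyz, residue, name, resname = NULL, chain = "A",
                          plddt = NULL) {
  n_res <- max(residue)
  resname <- resname %||% rep("ALA", n_res)
  residues <- data.frame(chain = chain, auth_seq = seq_len(n_res), icode = "",
                         resname = resname, seq_index = seq_len(n_res),
                         plddt = plddt %||% rep(NA_real_, n_res),
                         stringsAsFactors = FALSE)
  atoms <- data.frame(residue = residue, name = name,
                      element = substr(name, 1, 1),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      backbone = name %in% c("N", "CA", "C", "O", "OXT"),
                      stringsAsFactors = FALSE)
  structure(list(chains = unique(chain), residues = residues, atoms = atoms,
                 source_kind = if (is.null(plddt)) "experimental"
                               else "alphafold-model"),
            class = "protein_structure")
}

# --- partitions / modularity ------------------------------------------------

# all set partitions of n elements as restricted growth strings
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(a, mx) {
    if (length(a) == n) { out[[length(out) + 1L]] <<- a; return(invisible()) }
    for (v in seq_len(mx + 1L)) rec(c(a, v), max(mx, v))
  }
  rec(1L, 1L)
  out
}

bf_max_modularity <- function(graph, resolution) {
  n <- igraph::vcount(graph)
  best <- -Inf
  for (p in enumerate_partitions(n)) {
    q <- partition_modularity(graph, p, resolution)
    if (q > best) best <- q
  }
  best
}

weighted_graph <- function(n, edges, weights = NULL) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  igraph::add_edges(g, t(edges), weight = weights %||% rep(1, nrow(edges)))
}

two_clique_graph <- function() {
  el <- rbind(t(combn(1:5, 2)), t(combn(6:10, 2)), c(5, 6))
  weighted_graph(10, el, c(rep(1, 20), 0.1))
}

# 16-residue toy: two 8-residue blocks, confident everywhere, PAE low
# within blocks and just under the edge threshold between them, so the
# inter-block edges are weak: high resolution splits the blocks, low
# resolution merges them.
pae_two_block_structure <- function() {
  xyz <- cbind(seq_len(16) * 4, 0, 0)
  toy_structure(xyz, residue = seq_len(16), name = rep("CA", 16),
                plddt = rep(95, 16))
}

pae_two_block_matrix <- function() {
  pae <- matrix(4.5, 16, 16)
  blk <- outer(rep(1:2, each = 8), rep(1:2, each = 8), "==")
  pae[blk] <- 1
  diag(pae) <- 0.2
  pae
}

# --- 1-D clustering ---------------------------------------------------------

# exhaustive threshold-split oracle: minimal total within-cluster SS
bf_threshold_split <- function(scores) {
  v <- sort(unique(scores))
  ss <- function(x) if (length(x) < 2) 0 else sum((x - mean(x))^2)
  best <- Inf; high <- NULL
  for (t in v[-length(v)]) {
    lo <- scores[scores <= t]; hi <- scores[scores > t]
    w <- ss(lo) + ss(hi)
    if (w < best) { best <- w; high <- names(scores)[scores > t] }
  }
  list(high = high, within_ss = best)
}

# --- Mann-Whitney -----------------------------------------------------------

# enumeration oracle using the pairwise-comparison definition of U
# (not the rank-sum route used by the implementation)
bf_mw_greater <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); N <- length(pooled)
  ustat <- function(xs, ys) {
    u <- 0
    for (a in xs) for (b in ys) u <- u + (a > b) + 0.5 * (a == b)
    u
  }
  u_obs <- ustat(x, y)
  combos <- combn(N, n)
  hits <- 0
  for (k in seq_len(ncol(combos))) {
    xi <- combos[, k]
    if (ustat(pooled[xi], pooled[-xi]) >= u_obs - 1e-9) hits <- hits + 1
  }
  hits / ncol(combos)
}

# --- small TAC graphs -------------------------------------------------------

tac_from_pairs <- function(pairs, conservation) {
  acc <- sort(unique(c(pairs)))
  build_tac_graph(acc, pairs, conservation)
}

# public-field chain subsetter (the package keeps its own internal)
structure_chain_for_test <- function(st, chain) {
  keep_res <- which(st$residues$chain == chain)
  res <- st$residues[keep_res, , drop = FALSE]
  keep_at <- st$atoms$residue %in% keep_res
  at <- st$atoms[keep_at, , drop = FALSE]
  at$residue <- match(at$residue, keep_res)
  rownames(res) <- NULL; rownames(at) <- NULL
  st$residues <- res; st$atoms <- at; st$chains <- chain
  st
}

strip_timestamp <- function(path) {
  lines <- readLines(path)
  lines[!grepl("generated_at", lines)]
}
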