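pae_fixture <- function(n = 3, plddt = c(80, 60, 90)) {
  xyz <- cbind(seq_len(n) * 4, 0, 0)
  res <- rep(seq_len(n), each = 2)
  toy_structure(rbind(xyz, xyz + 1)[order(rep(seq_len(n), 2)), ],
                residue = res, name = rep(c("CA", "CB"), n),
                plddt = plddt)
}

test_that("PAE graph honours strict pLDDT and PAE thresholds and symmetrises", {
  st <- pae_fixture()
  pae <- matrix(3, 3, 3); diag(pae) <- 0.1
  g <- build_pae_graph(st, pae, plddt_min = 70, pae_max = 5)
  expect_setequal(igraph::V(g)$name, c("1", "3"))  # 60 fails, strictly

  # boundary: pLDDT exactly at threshold is excluded
  st2 <- pae_fixture(plddt = c(70, 70.0001, 90))
  g2 <- build_pae_graph(st2, pae)
  expect_setequal(igraph::V(g2)$name, c("2", "3"))

  # all PAE above threshold: nodes but no edges
  g3 <- build_pae_graph(pae_fixture(plddt = c(90, 90, 90)),
                        matrix(10, 3, 3))
  expect_equal(igraph::vcount(g3), 3)
  expect_equal(igraph::ecount(g3), 0)

  # boundary: symmetrised PAE exactly at 5 is excluded; below is kept
  pae4 <- matrix(10, 3, 3)
  pae4[1, 2] <- 4; pae4[2, 1] <- 6      # mean exactly 5 -> no edge
  pae4[1, 3] <- 2; pae4[3, 1] <- 4      # mean 3 -> weight 1/3
  g4 <- build_pae_graph(pae_fixture(plddt = c(90, 90, 90)), pae4)
  el <- igraph::as_edgelist(g4)
  expect_equal(nrow(el), 1)
  expect_setequal(el[1, ], c("1", "3"))
  expect_equal(igraph::E(g4)$weight, 1 / 3)

  # near-zero PAE floored at 0.2 before inversion
  pae5 <- matrix(10, 3, 3); pae5[1, 2] <- 0.01; pae5[2, 1] <- 0.01
  g5 <- build_pae_graph(pae_fixture(plddt = c(90, 90, 90)), pae5)
  expect_equal(igraph::E(g5)$weight, 1 / 0.2)

  expect_error(build_pae_graph(st, matrix(1, 2, 2)),
               class = "sp_dimension_error")
})

test_that("greedy modularity recovers planted cliques and known limits", {
  g <- two_clique_graph()
  memb <- detect_communities(g, resolution = 1)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[as.character(1:5)])), 1)
  expect_equal(length(unique(memb[as.character(6:10)])), 1)

  # resolution 0: whole connected graph collapses to one community
  memb0 <- detect_communities(g, resolution = 0)
  expect_equal(length(unique(memb0)), 1)

  # edgeless graph: all singletons
  ge <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(ge)$name <- as.character(1:4)
  expect_equal(length(unique(detect_communities(ge, 1))), 4)
})

test_that("greedy partition reaches >= 0.95 of the exhaustive optimum (<= 8 nodes)", {
  set.seed(1)
  for (rep in 1:4) {
    n <- sample(5:8, 1)
    g <- igraph::sample_gnp(n, 0.5)
    while (igraph::ecount(g) < 2) g <- igraph::sample_gnp(n, 0.5)
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.2, 2)
    igraph::V(g)$name <- as.character(seq_len(n))
    for (res in c(0.5, 1)) {
      memb <- detect_communities(g, res)
      q <- partition_modularity(g, memb[as.character(seq_len(n))], res)
      qstar <- bf_max_modularity(g, res)
      expect_gte(q, 0.95 * qstar - 1e-12)
      # and never above the true optimum
      expect_lte(q, qstar + 1e-12)
    }
  }
})

test_that("partition modularity beats the trivial partitions and matches igraph", {
  g <- two_clique_graph()
  for (res in c(0.3, 0.8, 1)) {
    memb <- detect_communities(g, res)[as.character(1:10)]
    q <- partition_modularity(g, memb, res)
    expect_gte(q, partition_modularity(g, rep(1, 10), res) - 1e-12)
    expect_gte(q, partition_modularity(g, 1:10, res) - 1e-12)
    expect_equal(q, igraph::modularity(g, memb, weights = igraph::E(g)$weight,
                                       resolution = res),
                 tolerance = 1e-12)
  }
})

test_that("decreasing resolution never increases the community count", {
  set.seed(2)
  g <- igraph::sample_gnp(14, 0.35)
  igraph::E(g)$weight <- runif(igraph::ecount(g), 0.2, 2)
  igraph::V(g)$name <- as.character(1:14)
  counts <- vapply(seq(1, 0, by = -0.1), function(r)
    length(unique(detect_communities(g, r))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("module filtering drops small communities and annotates survivors", {
  spec <- fixture_spec(seed = 21, n_modules = 2, residues_per_module = 45)
  fx <- make_structure(spec)
  g <- build_pae_graph(fx$structure, fx$pae)
  part <- detect_communities(g, resolution = 0.8)
  mods <- filter_modules(part, fx$structure, fx$pae, min_size = 30)
  expect_equal(length(mods), 2)
  expect_true(all(vapply(mods, function(m) length(m$residues), numeric(1)) >= 30))
  # disjoint and within pLDDT-passing residues
  all_res <- unlist(lapply(mods, `[[`, "residues"))
  expect_equal(anyDuplicated(all_res), 0)
  passing <- fx$structure$residues$seq_index[fx$structure$residues$plddt > 70]
  expect_true(all(all_res %in% passing))
  expect_true(all(diff(vapply(mods, function(m) length(m$residues), numeric(1))) <= 0))
  expect_lt(mods[[1]]$mean_pae, 5)

  # strict boundary: exactly min_size retained, one less dropped
  part2 <- c(rep(1, 30), rep(2, 29))
  names(part2) <- as.character(seq_len(59))
  st <- fx$structure; st$residues <- st$residues[1:59, ]
  mods2 <- filter_modules(part2, st, fx$pae[1:59, 1:59], min_size = 30)
  expect_equal(length(mods2), 1)
  expect_equal(length(mods2[[1]]$residues), 30)

  expect_equal(filter_modules(stats::setNames(integer(0), character(0)),
                              st, fx$pae[1:59, 1:59]), list())
})

test_that("resolution calibration returns the highest non-splitting value", {
  # one protein whose single reference domain is a clique: never split
  spec <- fixture_spec(seed = 31, residues_per_module = 40)
  fx <- make_structure(spec)
  r <- optimize_resolution(list(fx$structure), list(fx$pae),
                           list(rbind(c(1, 40))))
  expect_equal(r, 1.00)

  # two weakly-joined cliques annotated as one domain: splits at high
  # resolution; the scan must return exactly the first non-splitting r
  st <- pae_two_block_structure()
  pae <- pae_two_block_matrix()
  ann <- list(rbind(c(1, 16)))
  r2 <- optimize_resolution(list(st), list(pae), ann)
  expect_lt(r2, 1)
  # independent downward grid scan using the public community detector
  g <- build_pae_graph(st, pae)
  split_at <- function(r) {
    memb <- detect_communities(g, r)
    length(unique(memb[as.character(1:16)])) > 1
  }
  grid <- seq(1, 0, by = -0.01)
  expected <- grid[which(!vapply(grid, split_at, logical(1)))[1]]
  expect_equal(r2, expected)
  expect_true(split_at(round(r2 + 0.01, 2)))

  expect_error(optimize_resolution(list(), list(), list()),
               class = "sp_input_error")
})
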