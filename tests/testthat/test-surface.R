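test_that("tessellation handles minimal, interior-point and degenerate inputs", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  t1 <- triangulate(tet)
  expect_equal(nrow(t1), 1)
  expect_equal(surface_atoms(t1), 1:4)  # all faces boundary

  t2 <- triangulate(rbind(tet, colMeans(tet)))
  expect_equal(nrow(t2), 4)             # centroid splits into 4 tetrahedra
  expect_equal(surface_atoms(t2), 1:4)  # centroid in no boundary face

  expect_error(triangulate(tet[1:3, ]), class = "sp_degenerate_geometry_error")
  flat <- cbind(runif(8), runif(8), 0)
  expect_error(triangulate(flat), class = "sp_degenerate_geometry_error")
})

test_that("cubic 3x3x3 lattice: 26 outer points are surface, centre is not", {
  g <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  tt <- triangulate(g)
  surf <- surface_atoms(tt)
  centre <- which(g[, 1] == 1 & g[, 2] == 1 & g[, 3] == 1)
  expect_equal(surf, setdiff(1:27, centre))
  expect_equal(surf, bf_surface_atoms(tt))
})

test_that("tessellation satisfies face-multiplicity and empty-circumsphere invariants", {
  set.seed(10)
  for (n in c(12, 40, 80)) {
    pts <- matrix(rnorm(3 * n), ncol = 3)
    tt <- triangulate(pts)
    # every point is a vertex; faces occur in exactly 1 or 2 tetrahedra
    expect_setequal(unique(as.vector(tt)), seq_len(n))
    faces <- rbind(tt[, -1], tt[, -2], tt[, -3], tt[, -4])
    key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
    expect_true(all(table(key) <= 2))
    expect_equal(surface_atoms(tt), bf_surface_atoms(tt))
    pu <- attr(tt, "coords_used")
    # extreme points along random directions are hull vertices, hence surface
    for (k in 1:10) {
      d <- rnorm(3)
      expect_true(which.max(pu %*% d) %in% surface_atoms(tt))
    }
    # empty circumsphere (checked on the perturbed coordinates actually used)
    for (i in sample(nrow(tt), min(25, nrow(tt)))) {
      v <- pu[tt[i, ], ]
      M <- sweep(v[-1, , drop = FALSE], 2, v[1, ])
      cc <- v[1, ] + solve(M, rowSums(M^2) / 2)
      r2 <- sum((v[1, ] - cc)^2)
      d2 <- rowSums(sweep(pu, 2, cc)^2)
      inside <- which(d2 < r2 * (1 - 1e-9))
      expect_true(all(inside %in% tt[i, ]))
    }
  }
})

test_that("tessellation matches scipy.spatial.Delaunay on a generic cloud", {
  set.seed(33)
  pts <- matrix(rnorm(150), ncol = 3)
  tt <- triangulate(pts)
  pu <- attr(tt, "coords_used")
  csv <- tempfile(fileext = ".csv"); out <- tempfile(fileext = ".csv")
  utils::write.table(pu, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  code <- sprintf(paste0(
    "import numpy as np\nfrom scipy.spatial import Delaunay\n",
    "p = np.loadtxt('%s', delimiter=',')\n",
    "t = np.sort(Delaunay(p).simplices, axis=1) + 1\n",
    "np.savetxt('%s', t[np.lexsort(t.T[::-1])], fmt='%%d', delimiter=',')\n"),
    csv, out)
  py <- tempfile(fileext = ".py"); writeLines(code, py)
  status <- system2("python", py)
  expect_equal(status, 0)
  ref <- as.matrix(utils::read.table(out, sep = ","))
  mine <- t(apply(tt, 1, sort))
  mine <- mine[do.call(order, as.data.frame(mine)), ]
  dimnames(mine) <- NULL; dimnames(ref) <- NULL
  expect_equal(mine, ref)
})

test_that("side-chain accessibility ignores backbone exposure; glycine is special", {
  # 3x3x3 lattice as pseudo-atoms: residue 1 has a buried side chain and an
  # exposed backbone; residue 2 an exposed side chain; residue 3 is glycine
  # with only CA atoms.
  g <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  centre <- which(g[, 1] == 1 & g[, 2] == 1 & g[, 3] == 1)
  resid <- integer(27); nm <- character(27)
  resid[centre] <- 1; nm[centre] <- "CB"       # buried side chain
  corner <- which(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0)
  resid[corner] <- 1; nm[corner] <- "N"        # exposed backbone
  face <- which(g[, 1] == 2 & g[, 2] == 1 & g[, 3] == 1)
  resid[face] <- 2; nm[face] <- "CB"           # exposed side chain
  gly <- which(g[, 1] == 0 & g[, 2] == 2 & g[, 3] == 2)
  resid[gly] <- 3; nm[gly] <- "CA"             # glycine: backbone only
  rest <- which(resid == 0)
  resid[rest] <- 3 + seq_along(rest); nm[rest] <- "CB"
  st <- toy_structure(g, residue = resid, name = nm,
                      resname = c("ALA", "ALA", "GLY",
                                  rep("ALA", length(rest))))
  tt <- triangulate(g)
  surf <- surface_atoms(tt)
  acc <- accessible_residues(st, surf)
  expect_false(1 %in% acc)   # CB buried, backbone exposure does not count
  expect_true(2 %in% acc)
  expect_false(3 %in% acc)   # glycine: strictly never accessible
  accg <- accessible_residues(st, surf, glycine_ca_proxy = TRUE)
  expect_true(3 %in% accg)
})

test_that("residue adjacency requires shared tetrahedra between surface atoms", {
  # 4x3x3 lattice; two interior atoms share tetrahedra but belong to
  # residues whose surface atoms are at opposite ends of the block.
  g <- as.matrix(expand.grid(0:3, 0:2, 0:2))
  idx <- function(x, y, z) which(g[, 1] == x & g[, 2] == y & g[, 3] == z)
  resid <- integer(nrow(g)); nm <- character(nrow(g))
  resid[idx(0, 1, 1)] <- 1; nm[idx(0, 1, 1)] <- "CB"  # surface, residue 1
  resid[idx(1, 1, 1)] <- 1; nm[idx(1, 1, 1)] <- "CG"  # buried,  residue 1
  resid[idx(3, 1, 1)] <- 2; nm[idx(3, 1, 1)] <- "CB"  # surface, residue 2
  resid[idx(2, 1, 1)] <- 2; nm[idx(2, 1, 1)] <- "CG"  # buried,  residue 2
  resid[idx(0, 0, 0)] <- 3; nm[idx(0, 0, 0)] <- "CB"  # corner, residue 3
  resid[idx(0, 1, 0)] <- 4; nm[idx(0, 1, 0)] <- "CB"  # adjacent corner, res 4
  rest <- which(resid == 0)
  resid[rest] <- 4 + seq_along(rest); nm[rest] <- "CB"
  st <- toy_structure(g, residue = resid, name = nm)
  tt <- triangulate(g)
  surf <- surface_atoms(tt)
  acc <- accessible_residues(st, surf)
  adj <- residue_adjacency(st, tt, surf, acc)
  key <- paste(adj[, 1], adj[, 2])
  # residues 1 and 2: only their buried atoms share tetrahedra -> not adjacent
  expect_true(all(c(1, 2) %in% acc))
  expect_false("1 2" %in% key)
  # residues 3 and 4: neighbouring surface corners -> adjacent
  expect_true("3 4" %in% key)
  # irreflexive and symmetric-as-unordered
  expect_true(all(adj[, 1] < adj[, 2]))
})

test_that("module surface is connected under adjacency on realistic fixtures", {
  fx <- make_structure(fixture_spec(seed = 12, residues_per_module = 50))
  sm <- surface_model(fx$structure)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(sm$adjacency), ncol = 2), directed = FALSE)
  comp <- igraph::components(g)
  expect_equal(comp$no, 1)
  expect_setequal(as.integer(igraph::V(g)$name), sm$accessible_residues)
})

test_that("interface extraction agrees with brute force and is strict at 6 A", {
  st <- read_structure(mini_pdb())
  for (cut in c(4, 6, 8)) {
    expect_equal(interface_residues(st, "A", "B", cutoff = cut),
                 bf_interface(st, "A", "B", cut))
    expect_equal(interface_residues(st, "B", "A", cutoff = cut),
                 bf_interface(st, "B", "A", cut))
  }
  expect_error(interface_residues(st, "A", "Z"), class = "sp_chain_error")

  # exact boundary: atoms at exactly 6.0 A are excluded, 5.999 included
  xyz <- rbind(c(0, 0, 0), c(6, 0, 0), c(30, 0, 0), c(35.999, 0, 0))
  st2 <- toy_structure(xyz, residue = c(1, 2, 3, 4),
                       name = rep("CB", 4),
                       chain = c("A", "B", "A", "B"))
  st2$residues$chain <- c("A", "B", "A", "B")
  st2$chains <- c("A", "B")
  st2$residues$seq_index <- c(1, 1, 2, 2)
  expect_equal(interface_residues(st2, "A", "B", 6), 2L)
})
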