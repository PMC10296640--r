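# Surface geometry of a structural module: Delaunay tessellation of heavy
# atoms, boundary-face surface atoms, side-chain accessibility and residue
# adjacency.

#' 3-D Delaunay tessellation of a point set
#'
#' Tessellates the convex hull of the points into tetrahedra such that no
#' point lies strictly inside any tetrahedron's circumsphere. Input points
#' are internally centred, scaled, and perturbed by a deterministic
#' radial-inflation-plus-jitter term (a symbolic-perturbation surrogate)
#' so that degenerate inputs -- cospherical clusters, points lying on the
#' interior of flat hull facets -- resolve reproducibly; the perturbation
#' is far below coordinate precision for molecular input. The tessellation
#' is validated (every face shared by at most two tetrahedra, every point a
#' vertex of at least one) and rebuilt with a fresh perturbation stream on
#' the rare failure.
#'
#' @param coords Numeric matrix (n x 3) of coordinates in Angstrom.
#' @param jitter Relative magnitude of the deterministic perturbation
#'   (fraction of the bounding-box scale). Default `1e-6`; `0` disables it
#'   (only safe for points in general position).
#' @return Integer matrix (m x 4) of 1-based point indices, one tetrahedron
#'   per row, with the perturbed coordinates used attached as attribute
#'   `"coords_used"`.
#' @export
triangulate <- function(coords, jitter = 1e-6) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop2("coords must be n x 3", class = "sp_input_error")
  if (nrow(coords) < 4)
    stop2("need at least 4 points for a 3-D tessellation",
          class = "sp_degenerate_geometry_error")
  if (anyNA(coords)) stop2("missing coordinates", class = "sp_input_error")
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  sv <- svd(cc, nu = 0, nv = 0)$d
  if (sv[3] <= 1e-8 * max(sv[1], 1))
    stop2("points are (nearly) coplanar; 3-D tessellation is degenerate",
          class = "sp_degenerate_geometry_error")
  scale <- max(abs(cc))
  P0 <- cc / scale
  n <- nrow(P0)

  for (attempt in 1:6) {
    P <- P0
    if (jitter > 0) {
      rad <- sqrt(rowSums(P^2))
      u <- P / pmax(rad, 1e-12)
      u[rad < 1e-12, ] <- 0
      noise <- matrix(det_uniform(3L * n, stream = attempt) - 0.5, n, 3)
      # inflation dominates the random term so hull-facet interior points
      # move outward, never inward
      P <- P + (20 * jitter) * u + jitter * noise
    }
    ans <- .delaunay3d_cpp(P)
    if (ans$status == 0) {
      tets <- ans$tets
      if (valid_tessellation(tets, n)) {
        attr(tets, "coords_used") <- sweep(P * scale, 2, ctr, "+")
        return(tets)
      }
    }
    if (jitter == 0) break
  }
  stop2("Delaunay tessellation failed (degenerate geometry not resolved ",
        "by perturbation)", class = "sp_degenerate_geometry_error")
}

valid_tessellation <- function(tets, n) {
  if (!nrow(tets)) return(FALSE)
  if (!all(sort(unique(as.vector(tets))) %in% seq_len(n))) return(FALSE)
  if (length(unique(as.vector(tets))) != n) return(FALSE)
  fc <- face_counts(tets)
  all(fc$count <= 2L)
}

# enumerate the 4 faces of each tetrahedron; returns unique faces + counts
face_counts <- function(tets) {
  m <- nrow(tets)
  faces <- rbind(tets[, c(2, 3, 4), drop = FALSE],
                 tets[, c(1, 3, 4), drop = FALSE],
                 tets[, c(1, 2, 4), drop = FALSE],
                 tets[, c(1, 2, 3), drop = FALSE])
  faces <- t(apply(faces, 1, sort))
  key <- paste(faces[, 1], faces[, 2], faces[, 3])
  tab <- table(key)
  first <- !duplicated(key)
  list(faces = faces[first, , drop = FALSE],
       key = key[first],
       count = as.integer(tab[key[first]]),
       all_key = key)
}

#' Surface atoms of a tessellation
#'
#' The boundary of a tessellation consists of the faces that belong to
#' exactly one tetrahedron; the surface atoms are the union of the vertices
#' of those faces. Convex-hull vertices are always included.
#'
#' @param tets Tetrahedron index matrix from [triangulate()].
#' @return Sorted integer vector of surface point indices.
#' @export
surface_atoms <- function(tets) {
  fc <- face_counts(tets)
  boundary <- fc$faces[fc$count == 1L, , drop = FALSE]
  sort(unique(as.vector(boundary)))
}

#' Side-chain accessible residues
#'
#' A residue is accessible when at least one of its side-chain heavy atoms
#' is a surface atom; backbone-only exposure does not qualify. Glycine has
#' no side-chain heavy atom and is therefore never accessible under the
#' strict rule; `glycine_ca_proxy = TRUE` opts in to treating glycine's CA
#' as a side-chain stand-in.
#'
#' @param structure A `protein_structure` (the structural module).
#' @param surface Surface atom indices (rows of `structure$atoms`), as from
#'   [surface_atoms()].
#' @param glycine_ca_proxy Treat glycine CA as side-chain. Default `FALSE`.
#' @return Sorted integer vector of accessible residue sequence indices.
#' @export
accessible_residues <- function(structure, surface, glycine_ca_proxy = FALSE) {
  at <- structure$atoms
  sidechain <- !at$backbone
  if (glycine_ca_proxy) {
    gly <- structure$residues$resname[at$residue] == "GLY"
    sidechain <- sidechain | (gly & at$name == "CA")
  }
  hits <- intersect(surface, which(sidechain))
  sort(unique(structure$residues$seq_index[at$residue[hits]]))
}

#' Residue adjacency from shared tetrahedra
#'
#' Two accessible residues are neighbours when some tetrahedron of the
#' tessellation contains a surface atom of each. Burial-mediated
#' co-occurrence does not count: only surface atoms within the shared
#' tetrahedron establish adjacency.
#'
#' @param structure The structural module.
#' @param tets Tessellation from [triangulate()].
#' @param surface Surface atom indices.
#' @param accessible Accessible residue sequence indices.
#' @return Two-column integer matrix of unordered residue pairs
#'   (`seq_index`), each pair once with the smaller index first.
#' @export
residue_adjacency <- function(structure, tets, surface, accessible) {
  at <- structure$atoms
  res_of_atom <- structure$residues$seq_index[at$residue]
  is_surf <- logical(nrow(at))
  is_surf[surface] <- TRUE
  ok_res <- res_of_atom %in% accessible

  out <- matrix(integer(0), 0, 2)
  acc <- list()
  for (t in seq_len(nrow(tets))) {
    a <- tets[t, ]
    a <- a[is_surf[a] & ok_res[a]]
    if (length(a) < 2) next
    rs <- sort(unique(res_of_atom[a]))
    if (length(rs) < 2) next
    cmb <- utils::combn(rs, 2)
    acc[[length(acc) + 1L]] <- t(cmb)
  }
  if (!length(acc)) return(out)
  m <- unique(do.call(rbind, acc))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' One-call surface model of a structural module
#'
#' Convenience wrapper running [triangulate()], [surface_atoms()],
#' [accessible_residues()] and [residue_adjacency()] on the heavy atoms of
#' one structural module.
#'
#' @param structure The structural module (a `protein_structure`).
#' @param glycine_ca_proxy See [accessible_residues()].
#' @return A `surface_model` list: `tetrahedra`, `surface_atoms`,
#'   `accessible_residues`, `adjacency`.
#' @export
surface_model <- function(structure, glycine_ca_proxy = FALSE) {
  coords <- as.matrix(structure$atoms[, c("x", "y", "z")])
  tets <- triangulate(coords)
  surf <- surface_atoms(tets)
  acc <- accessible_residues(structure, surf, glycine_ca_proxy)
  adj <- residue_adjacency(structure, tets, surf, acc)
  structure(list(tetrahedra = tets, surface_atoms = surf,
                 accessible_residues = acc, adjacency = adj),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat("<surface_model> ", nrow(x$tetrahedra), " tetrahedra, ",
      length(x$surface_atoms), " surface atoms, ",
      length(x$accessible_residues), " accessible residues, ",
      nrow(x$adjacency), " adjacency pairs\n", sep = "")
  invisible(x)
}

#' Interface residues between two chains
#'
#' Benchmark support: a residue of `chain_a` belongs to the interface with
#' `chain_b` when any of its heavy atoms lies strictly closer than `cutoff`
#' Angstrom to any heavy atom of `chain_b`.
#'
#' @param complex A multi-chain `protein_structure`.
#' @param chain_a,chain_b Chain identifiers.
#' @param cutoff Distance cutoff in Angstrom (strict `<`). Default 6.
#' @return Sorted integer vector of `chain_a` residue sequence indices.
#' @export
interface_residues <- function(complex, chain_a, chain_b, cutoff = 6) {
  for (ch in c(chain_a, chain_b))
    if (!ch %in% complex$chains)
      stop2("chain '", ch, "' not present; available: ",
            paste(complex$chains, collapse = ", "), class = "sp_chain_error")
  at <- complex$atoms
  res_chain <- complex$residues$chain[at$residue]
  A <- which(res_chain == chain_a)
  B <- which(res_chain == chain_b)
  xyzA <- as.matrix(at[A, c("x", "y", "z")])
  xyzB <- as.matrix(at[B, c("x", "y", "z")])
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), "+") - 2 * xyzA %*% t(xyzB)
  mind2 <- apply(d2, 1, min)
  hit <- A[mind2 < cutoff^2 - 1e-12]
  sort(unique(complex$residues$seq_index[at$residue[hit]]))
}
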