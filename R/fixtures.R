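# Deterministic synthetic fixtures: stylised pseudo-proteins with a buried
# core, a spatially contiguous surface patch of elevated conservation, a
# block-structured PAE matrix, and a matching orthologue alignment plus
# star guide tree. Everything flows from a single seed and is written in
# the standard formats so the real readers are exercised.

#' Fixture generation parameters
#'
#' Collects the knobs of the synthetic world: module count and size, the
#' planted patch size, target identity-to-query on patch and background
#' columns, column-level noise, orthologue count, and the intra/inter
#' module PAE levels. Defaults describe a single 60-residue module with a
#' 12-residue patch at 0.9 identity over a 0.4 background, 50 orthologues,
#' and a sharp PAE block structure (2 A within, 20 A between modules).
#'
#' @param seed Integer seed; all fixture randomness derives from it.
#' @param n_modules Number of structural modules.
#' @param residues_per_module Residues per module (must exceed
#'   `patch_size`).
#' @param patch_size Planted patch size in residues.
#' @param patch_conservation_mean,background_conservation_mean Expected
#'   per-column identity to the query, in \[0, 1\].
#' @param conservation_noise_sd Truncated-normal sd of the per-column
#'   identity targets.
#' @param n_orthologues Orthologue sequences in the alignment.
#' @param pae_intra,pae_inter PAE levels in Angstrom within and between
#'   modules.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_modules = 1L, residues_per_module = 60L,
                         patch_size = 12L, patch_conservation_mean = 0.9,
                         background_conservation_mean = 0.4,
                         conservation_noise_sd = 0.05, n_orthologues = 50L,
                         pae_intra = 2, pae_inter = 20) {
  stopifnot(patch_size < residues_per_module,
            patch_conservation_mean >= 0, patch_conservation_mean <= 1,
            background_conservation_mean >= 0,
            background_conservation_mean <= 1)
  structure(list(seed = as.integer(seed), n_modules = as.integer(n_modules),
                 residues_per_module = as.integer(residues_per_module),
                 patch_size = as.integer(patch_size),
                 patch_conservation_mean = patch_conservation_mean,
                 background_conservation_mean = background_conservation_mean,
                 conservation_noise_sd = conservation_noise_sd,
                 n_orthologues = as.integer(n_orthologues),
                 pae_intra = pae_intra, pae_inter = pae_inter),
            class = "fixture_spec")
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate a synthetic structural model and PAE matrix
#'
#' Builds a pseudo-protein of `n_modules` spatially separated globules.
#' Each module places most residues on a jittered quasi-uniform sphere
#' (radius set so neighbour spacing is about 6 Angstrom) and a minority in
#' a buried core. A residue is four backbone pseudo-atoms slightly inside
#' its anchor point plus two side-chain pseudo-atoms pointing outward, so
#' surface residues expose side chains and core residues stay buried. The
#' planted patch is the spherical cap of `patch_size` surface residues
#' around a fixed direction, hence spatially contiguous. The PAE matrix is
#' block structured: `pae_intra` within modules, `pae_inter` between, with
#' seeded asymmetric noise.
#'
#' @param spec A [fixture_spec()].
#' @return List with `structure` (a `protein_structure` with pLDDT),
#'   `pae` (matrix), `planted` (list of patch residue index vectors, one
#'   per module) and `spec`.
#' @export
make_structure <- function(spec) {
  local_seed(spec$seed, {
    nm <- spec$n_modules
    npm <- spec$residues_per_module
    aas <- setdiff(names(AA3), "GLY")
    res_list <- list(); atom_list <- list(); planted <- list()
    rid0 <- 0L
    for (mod in seq_len(nm)) {
      n_core <- max(4L, round(0.15 * npm))
      n_surf <- npm - n_core
      R <- sqrt(n_surf * 36 / (4 * pi))
      dirs <- fibonacci_sphere(n_surf)
      pos_surf <- dirs * R + matrix(stats::rnorm(3 * n_surf, 0, 0.45), n_surf)
      core_dirs <- fibonacci_sphere(n_core)
      pos_core <- core_dirs * (R * 0.33) +
        matrix(stats::rnorm(3 * n_core, 0, 0.4), n_core)
      pos <- rbind(pos_surf, pos_core)
      offset <- c((mod - 1) * (4 * R + 20), 0, 0)
      # planted patch: cap of nearest surface residues around direction 1
      cap <- order(-(dirs %*% dirs[1, ]))[seq_len(spec$patch_size)]
      planted[[mod]] <- sort(rid0 + cap)

      for (i in seq_len(npm)) {
        p <- pos[i, ]
        u <- p / sqrt(sum(p^2))
        t1 <- c(-u[2], u[1], 0)
        if (sum(t1^2) < 1e-6) t1 <- c(1, 0, 0)
        t1 <- t1 / sqrt(sum(t1^2))
        t2 <- c(u[2] * t1[3] - u[3] * t1[2], u[3] * t1[1] - u[1] * t1[3],
                u[1] * t1[2] - u[2] * t1[1])
        xyz <- rbind(
          N  = p - 1.3 * u + 0.5 * t1,
          CA = p - 0.9 * u,
          C  = p - 1.3 * u - 0.5 * t1,
          O  = p - 1.7 * u + 0.5 * t2,
          CB = p + 0.3 * u + 0.2 * t1,
          CG = p + 1.5 * u
        )
        xyz <- xyz + matrix(stats::rnorm(18, 0, 0.12), 6)
        xyz <- sweep(xyz, 2, offset, "+")
        atom_list[[rid0 + i]] <- data.frame(
          residue = rid0 + i, name = rownames(xyz), element = "C",
          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
          backbone = rownames(xyz) %in% BACKBONE_ATOMS,
          stringsAsFactors = FALSE)
      }
      res_list[[mod]] <- data.frame(
        chain = "A", auth_seq = rid0 + seq_len(npm), icode = "",
        resname = sample(aas, npm, replace = TRUE),
        seq_index = rid0 + seq_len(npm),
        plddt = round(stats::runif(npm, 85, 98), 2),
        stringsAsFactors = FALSE)
      rid0 <- rid0 + npm
    }
    residues <- do.call(rbind, res_list)
    atoms <- do.call(rbind, atom_list)
    atoms$element <- ifelse(atoms$name %in% c("N"), "N",
                            ifelse(atoms$name == "O", "O", "C"))
    st <- new_protein_structure(residues, atoms, "alphafold-model")

    n <- nrow(residues)
    module_of <- rep(seq_len(nm), each = npm)
    same <- outer(module_of, module_of, "==")
    pae <- matrix(spec$pae_inter, n, n) +
      matrix(stats::runif(n * n, -1, 1), n, n)
    intra <- spec$pae_intra + matrix(stats::runif(n * n, -0.5, 0.5), n, n)
    pae[same] <- intra[same]
    pae <- pmax(pae, 0.2)
    diag(pae) <- 0.2

    list(structure = st, pae = pae, planted = planted, spec = spec)
  })
}

#' Generate a synthetic orthologue alignment and guide tree
#'
#' The query sequence is read off the fixture structure's residue types.
#' Each alignment column draws a target identity from a truncated normal
#' centred on the patch or background mean; each orthologue then matches
#' the query with that probability or carries a uniformly drawn different
#' amino acid (no gaps are introduced, so column coverage is full). The
#' guide tree is a star with randomised branch lengths, giving
#' non-uniform but exchangeable orthologue weights.
#'
#' @param spec A [fixture_spec()].
#' @param fixture Output of [make_structure()] (for the query sequence and
#'   the planted patch columns).
#' @param query_id Identifier for the query row. Default `"query"`.
#' @return List with `alignment` (an `alignment`), `tree` (phylo) and
#'   `target_identity` (per-column probability used).
#' @export
make_alignment <- function(spec, fixture, query_id = "query") {
  seed2 <- (spec$seed + 499979) %% 2147483647
  local_seed(seed2, {
    res <- fixture$structure$residues
    qaa <- unname(AA3[res$resname])
    n <- length(qaa)
    patch_cols <- sort(unlist(fixture$planted))
    mu <- rep(spec$background_conservation_mean, n)
    mu[patch_cols] <- spec$patch_conservation_mean
    p <- stats::rnorm(n, mu, spec$conservation_noise_sd)
    p <- pmin(pmax(p, 0.01), 0.999)
    alphabet <- unname(AA3)
    ids <- sprintf("orth%03d", seq_len(spec$n_orthologues))
    seqs <- character(spec$n_orthologues)
    for (s in seq_len(spec$n_orthologues)) {
      match_mask <- stats::runif(n) < p
      chars <- qaa
      nmis <- sum(!match_mask)
      if (nmis) {
        sub <- vapply(which(!match_mask), function(i)
          sample(setdiff(alphabet, qaa[i]), 1L), character(1))
        chars[!match_mask] <- sub
      }
      seqs[s] <- paste(chars, collapse = "")
    }
    all_seqs <- stats::setNames(c(paste(qaa, collapse = ""), seqs),
                                c(query_id, ids))
    aln <- structure(list(seqs = all_seqs, query_id = query_id),
                     class = "alignment")
    bl <- stats::runif(spec$n_orthologues, 0.5, 2)
    newick <- paste0("(", query_id, ":0.05,",
                     paste(sprintf("%s:%.4f", ids, bl), collapse = ","), ");")
    tree <- ape::read.tree(text = newick)
    list(alignment = aln, tree = tree, target_identity = p)
  })
}

#' Write an alignment as aligned FASTA
#'
#' @param alignment An `alignment` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(alignment$seqs))
    writeLines(c(paste0(">", id), alignment$seqs[[id]]), con)
  invisible(path)
}

#' Materialise a complete fixture set on disk
#'
#' Generates structure + PAE + alignment + tree for a [fixture_spec()] and
#' writes them in the standard formats (PDB, AlphaFold-style PAE JSON,
#' aligned FASTA, Newick), so pipeline runs exercise the real readers.
#'
#' @param spec A `fixture_spec`.
#' @param dir Output directory (created if needed).
#' @param pae_dialect Passed to [write_pae_json()].
#' @return Named list of file paths (`model`, `pae`, `alignment`, `tree`)
#'   plus the in-memory `fixture` and `msa` objects.
#' @export
write_fixture_set <- function(spec, dir, pae_dialect = "nested") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- make_structure(spec)
  al <- make_alignment(spec, fx)
  paths <- list(model = file.path(dir, "model.pdb"),
                pae = file.path(dir, "pae.json"),
                alignment = file.path(dir, "alignment.fasta"),
                tree = file.path(dir, "tree.nwk"))
  write_pdb(fx$structure, paths$model)
  write_pae_json(fx$pae, paths$pae, dialect = pae_dialect)
  write_alignment_fasta(al$alignment, paths$alignment)
  ape::write.tree(al$tree, paths$tree)
  c(paths, list(fixture = fx, msa = al))
}
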