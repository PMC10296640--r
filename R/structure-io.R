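#' @useDynLib surfpatch, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

new_protein_structure <- function(residues, atoms, source_kind) {
  stopifnot(is.data.frame(residues), is.data.frame(atoms))
  structure(list(
    chains = unique(residues$chain),
    residues = residues,
    atoms = atoms,
    source_kind = source_kind
  ), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure> ", nrow(x$residues), " residues, ",
      nrow(x$atoms), " heavy atoms, chains: ",
      paste(x$chains, collapse = ", "),
      " [", x$source_kind, "]\n", sep = "")
  invisible(x)
}

#' Read a protein structural model
#'
#' Parses a PDB or mmCIF file into the internal structure representation:
#' amino-acid residues with their heavy atoms. Hydrogens (and deuterium) are
#' discarded, HETATM ligands and waters are dropped, alternate locations are
#' resolved to the highest-occupancy conformer (ties broken by altloc
#' identifier order) and only the first model of multi-model files is kept.
#' Backbone atoms are `N`, `CA`, `C`, `O` and `OXT`; every other heavy atom
#' is classified as side-chain.
#'
#' For AlphaFold-style models the per-residue confidence (pLDDT, 0-100) is
#' read from the B-factor field. By default the source kind is inferred: a
#' file in which every residue carries a single constant B-factor in
#' \[0, 100\] is treated as a predicted model, anything else as an
#' experimental structure (for which `plddt` is `NA`).
#'
#' @param path Path to the structure file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension).
#' @param source_kind `"auto"`, `"alphafold-model"` or `"experimental"`.
#' @return An object of class `protein_structure` with elements `chains`,
#'   `residues` (chain, author number, insertion code, 3-letter code,
#'   1-based per-chain `seq_index`, `plddt`), `atoms` (name, element,
#'   coordinates in Angstrom, `backbone` flag, `residue` row index) and
#'   `source_kind`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           source_kind = c("auto", "alphafold-model",
                                           "experimental")) {
  format <- match.arg(format)
  source_kind <- match.arg(source_kind)
  if (!file.exists(path)) stop2("file not found: ", path, class = "sp_io_error")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  tab <- if (format == "pdb") parse_pdb_atoms(path) else parse_mmcif_atoms(path)
  build_structure(tab, source_kind)
}

parse_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  # first model only
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) > 1) {
    endm <- which(trimws(rec) == "ENDMDL")
    last <- if (length(endm)) endm[1] else length(lines)
    keepmask <- seq_along(lines) <= last
    lines <- lines[keepmask]; rec <- rec[keepmask]
  }
  idx <- which(rec == "ATOM  ")
  if (!length(idx))
    stop2("no protein ATOM records found in ", path,
          class = "sp_empty_structure_error")
  ln <- lines[idx]
  fx <- function(a, b) substr(ln, a, b)
  x <- suppressWarnings(as.numeric(fx(31, 38)))
  y <- suppressWarnings(as.numeric(fx(39, 46)))
  z <- suppressWarnings(as.numeric(fx(47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop2("unparseable ATOM coordinates at line ", idx[bad[1]], " of ", path,
          class = "sp_parse_error")
  occ <- suppressWarnings(as.numeric(fx(55, 60)))
  occ[is.na(occ)] <- 1
  bfac <- suppressWarnings(as.numeric(fx(61, 66)))
  elem <- toupper(trimws(fx(77, 78)))
  data.frame(
    name = trimws(fx(13, 16)),
    altloc = trimws(fx(17, 17)),
    resname = toupper(trimws(fx(18, 20))),
    chain = trimws(fx(22, 22)),
    auth_seq = suppressWarnings(as.integer(trimws(fx(23, 26)))),
    icode = trimws(fx(27, 27)),
    x = x, y = y, z = z, occ = occ, bfac = bfac, element = elem,
    stringsAsFactors = FALSE
  )
}

# Minimal tokenizer for mmCIF data rows (handles '...' and "..." quoting).
cif_tokens <- function(line) {
  out <- character(0)
  s <- line
  repeat {
    s <- sub("^[ \t]+", "", s)
    if (!nzchar(s)) break
    ch <- substr(s, 1, 1)
    if (ch == "'" || ch == "\"") {
      rest <- substr(s, 2, nchar(s))
      pos <- regexpr(paste0(ch, "([ \t]|$)"), rest)
      if (pos < 0) { out <- c(out, rest); break }
      out <- c(out, substr(rest, 1, pos - 1))
      s <- substr(rest, pos + 1, nchar(rest))
    } else {
      pos <- regexpr("[ \t]", s)
      if (pos < 0) { out <- c(out, s); break }
      out <- c(out, substr(s, 1, pos - 1))
      s <- substr(s, pos, nchar(s))
    }
  }
  out
}

parse_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L; n <- length(lines)
  tags <- character(0); rows <- list()
  while (i <= n) {
    if (trimws(lines[i]) == "loop_") {
      j <- i + 1L; tg <- character(0)
      while (j <= n && startsWith(trimws(lines[j]), "_")) {
        tg <- c(tg, trimws(lines[j])); j <- j + 1L
      }
      if (length(tg) && all(startsWith(tg, "_atom_site."))) {
        tags <- sub("^_atom_site\\.", "", tg)
        buf <- character(0)
        while (j <= n) {
          lt <- trimws(lines[j])
          if (!nzchar(lt) || startsWith(lt, "#") || lt == "loop_" ||
              startsWith(lt, "_")) break
          buf <- c(buf, cif_tokens(lines[j]))
          while (length(buf) >= length(tags)) {
            rows[[length(rows) + 1L]] <- buf[seq_along(tags)]
            buf <- buf[-seq_along(tags)]
          }
          j <- j + 1L
        }
        if (length(buf))
          stop2("ragged _atom_site loop near line ", j, " of ", path,
                class = "sp_parse_error")
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(rows))
    stop2("no _atom_site loop found in ", path, class = "sp_parse_error")
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  g <- function(nm, alt = NULL) {
    if (nm %in% tags) m[, nm]
    else if (!is.null(alt) && alt %in% tags) m[, alt]
    else rep(NA_character_, nrow(m))
  }
  grp <- g("group_PDB")
  keep <- is.na(grp) | grp == "ATOM"
  m <- m[keep, , drop = FALSE]
  if (!nrow(m))
    stop2("no protein ATOM records found in ", path,
          class = "sp_empty_structure_error")
  mdl <- g("pdbx_PDB_model_num")[keep]
  if (!all(is.na(mdl))) {
    first <- mdl[!is.na(mdl)][1]
    m <- m[is.na(mdl) | mdl == first, , drop = FALSE]
  }
  g2 <- function(nm, alt = NULL) {
    v <- if (nm %in% tags) m[, nm]
         else if (!is.null(alt) && alt %in% tags) m[, alt]
         else rep(NA_character_, nrow(m))
    v[v %in% c(".", "?")] <- ""
    v
  }
  num <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    if (anyNA(out))
      stop2("unparseable ", what, " in _atom_site loop of ", path,
            class = "sp_parse_error")
    out
  }
  occ <- suppressWarnings(as.numeric(g2("occupancy")))
  occ[is.na(occ)] <- 1
  data.frame(
    name = g2("auth_atom_id", "label_atom_id"),
    altloc = g2("label_alt_id"),
    resname = toupper(g2("auth_comp_id", "label_comp_id")),
    chain = g2("auth_asym_id", "label_asym_id"),
    auth_seq = as.integer(num(g2("auth_seq_id", "label_seq_id"), "residue number")),
    icode = g2("pdbx_PDB_ins_code"),
    x = num(g2("Cartn_x"), "coordinate"),
    y = num(g2("Cartn_y"), "coordinate"),
    z = num(g2("Cartn_z"), "coordinate"),
    occ = occ,
    bfac = suppressWarnings(as.numeric(g2("B_iso_or_equiv"))),
    element = toupper(g2("type_symbol")),
    stringsAsFactors = FALSE
  )
}

guess_element <- function(name) {
  stripped <- gsub("[0-9']", "", name)
  toupper(substr(stripped, 1, 1))
}

build_structure <- function(tab, source_kind) {
  # element fallback from atom name, then drop hydrogens
  noel <- !nzchar(tab$element) | is.na(tab$element)
  tab$element[noel] <- guess_element(tab$name[noel])
  tab <- tab[!(tab$element %in% c("H", "D")), , drop = FALSE]
  # drop waters however they were recorded
  tab <- tab[!(tab$resname %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!nrow(tab))
    stop2("no heavy protein atoms left after filtering",
          class = "sp_empty_structure_error")

  # altloc: keep the highest-occupancy conformer per (chain, residue, atom),
  # then restore the original file order
  key <- paste(tab$chain, tab$auth_seq, tab$icode, tab$name, sep = "\r")
  orig <- seq_len(nrow(tab))
  ord <- order(key, -tab$occ, tab$altloc)
  keep <- ord[!duplicated(key[ord])]
  tab <- tab[sort(keep), , drop = FALSE]

  # group atoms by residue in order of first appearance
  rkey <- paste(tab$chain, tab$auth_seq, tab$icode, sep = "\r")
  rid <- match(rkey, unique(rkey))
  tab <- tab[order(rid), , drop = FALSE]
  rid <- sort(rid)

  residues <- data.frame(
    chain = tab$chain[!duplicated(rid)],
    auth_seq = tab$auth_seq[!duplicated(rid)],
    icode = tab$icode[!duplicated(rid)],
    resname = tab$resname[!duplicated(rid)],
    stringsAsFactors = FALSE
  )
  residues$seq_index <- stats::ave(seq_len(nrow(residues)), residues$chain,
                                   FUN = seq_along)

  atoms <- data.frame(
    residue = rid,
    name = tab$name,
    element = tab$element,
    x = tab$x, y = tab$y, z = tab$z,
    backbone = tab$name %in% BACKBONE_ATOMS,
    stringsAsFactors = FALSE
  )

  # per-residue B-factor (pLDDT candidate): constant within residue?
  bconst <- as.numeric(tapply(tab$bfac, factor(rid, levels = seq_len(max(rid))),
                              function(b)
    if (all(is.na(b))) NA_real_
    else if (max(b, na.rm = TRUE) - min(b, na.rm = TRUE) < 1e-9) b[1]
    else NA_real_))
  looks_af <- !anyNA(bconst) && all(bconst >= 0 & bconst <= 100)
  kind <- switch(source_kind,
                 "auto" = if (looks_af) "alphafold-model" else "experimental",
                 source_kind)
  if (kind == "alphafold-model" && anyNA(bconst))
    stop2("alphafold-model requested but per-residue pLDDT could not be read ",
          "from the B-factor field", class = "sp_parse_error")
  residues$plddt <- if (kind == "alphafold-model") bconst else NA_real_

  new_protein_structure(residues, atoms, kind)
}

#' Write a structure as a PDB file
#'
#' Serialises a `protein_structure` back to fixed-column PDB `ATOM` records
#' (coordinates at PDB precision, 3 decimals). For predicted models the
#' per-residue pLDDT is written into the B-factor field. Used by the fixture
#' generator and for round-trip testing.
#'
#' @param structure A `protein_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  res <- structure$residues
  at <- structure$atoms
  b <- res$plddt[at$residue]
  b[is.na(b)] <- 0
  nm <- at$name
  # standard PDB atom-name justification: element columns 13-14
  nm_fmt <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), nm_fmt, res$resname[at$residue],
    res$chain[at$residue], res$auth_seq[at$residue],
    ifelse(nzchar(res$icode[at$residue]), res$icode[at$residue], " "),
    at$x, at$y, at$z, 1, b, at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a predicted aligned error (PAE) matrix
#'
#' Reads an AlphaFold-DB style JSON file in either of the two public
#' dialects: the nested-list form (`predicted_aligned_error` as an n x n
#' array) or the flat paired form (`residue1`/`residue2`/`distance`
#' vectors). Both produce identical dense matrices.
#'
#' @param path Path to the JSON file.
#' @return An n x n numeric matrix of expected positional errors in
#'   Angstrom, indexed by 1-based residue sequence position. The matrix may
#'   be asymmetric.
#' @export
read_pae <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (!is.null(names(obj)) && is.null(obj$predicted_aligned_error) &&
      is.null(obj$residue1) && length(obj) == 1L)
    obj <- obj[[1]]
  if (is.list(obj) && is.null(names(obj)) && length(obj) >= 1L)
    obj <- obj[[1]]
  m <- NULL
  if (!is.null(obj$predicted_aligned_error)) {
    pae <- obj$predicted_aligned_error
    if (is.list(pae)) {
      lens <- lengths(pae)
      if (length(unique(lens)) != 1L || lens[1] != length(pae))
        stop2("predicted_aligned_error payload is not square",
              class = "sp_format_error")
      m <- do.call(rbind, pae)
    } else m <- as.matrix(pae)
    if (nrow(m) != ncol(m))
      stop2("predicted_aligned_error payload is not square",
            class = "sp_format_error")
  } else if (!is.null(obj$residue1)) {
    r1 <- unlist(obj$residue1); r2 <- unlist(obj$residue2)
    d <- unlist(obj$distance)
    if (length(r1) != length(r2) || length(r1) != length(d))
      stop2("residue1/residue2/distance lengths differ",
            class = "sp_format_error")
    n <- max(r1, r2)
    if (length(d) != n * n || !setequal(unique(r1), seq_len(n)))
      stop2("flat PAE payload of length ", length(d),
            " does not cover an n x n grid", class = "sp_format_error")
    m <- matrix(NA_real_, n, n)
    m[cbind(r1, r2)] <- d
    if (anyNA(m))
      stop2("flat PAE payload leaves unfilled cells", class = "sp_format_error")
  } else {
    stop2("unrecognised PAE JSON dialect", class = "sp_format_error")
  }
  storage.mode(m) <- "double"
  if (any(m < 0)) stop2("negative PAE entries", class = "sp_format_error")
  dimnames(m) <- NULL
  m
}

#' Write a PAE matrix as AlphaFold-DB style JSON
#'
#' @param pae An n x n numeric matrix.
#' @param path Output path.
#' @param dialect `"nested"` (`predicted_aligned_error` array) or `"flat"`
#'   (`residue1`/`residue2`/`distance` vectors).
#' @return `path`, invisibly.
#' @export
write_pae_json <- function(pae, path, dialect = c("nested", "flat")) {
  dialect <- match.arg(dialect)
  n <- nrow(pae)
  obj <- if (dialect == "nested") {
    list(list(predicted_aligned_error = pae,
              max_predicted_aligned_error = max(pae)))
  } else {
    idx <- expand.grid(j = seq_len(n), i = seq_len(n))  # row-major pairs
    list(list(residue1 = idx$i, residue2 = idx$j,
              distance = pae[cbind(idx$i, idx$j)]))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a residue offset map
#'
#' Two-column TSV (author residue number, target sequence position) used as
#' a lightweight substitute for a full structure-to-sequence cross-mapping
#' service when PDB numbering differs from the alignment numbering.
#'
#' @param path Path to the TSV file (optional header line allowed).
#' @return A data frame with columns `auth_seq` and `target`.
#' @export
read_offset_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop2("offset map needs two columns", class = "sp_format_error")
  if (!is.numeric(tab[[1]])) tab <- tab[-1, , drop = FALSE]  # header line
  data.frame(auth_seq = as.integer(tab[[1]]), target = as.integer(tab[[2]]))
}

#' Renumber structure residues through an offset map
#'
#' Replaces per-chain sequence indices by user-supplied target positions
#' (e.g. UniProt numbering), so that structure residues line up with an
#' alignment computed on the full-length sequence. Residues not covered by
#' the map are dropped with a warning.
#'
#' @param structure A `protein_structure` (typically a single chain).
#' @param offset_map Data frame with columns `auth_seq` and `target`, as
#'   from [read_offset_map()].
#' @return The renumbered `protein_structure`.
#' @export
map_positions <- function(structure, offset_map) {
  if (anyDuplicated(offset_map$target))
    stop2("duplicate target positions in offset map", class = "sp_mapping_error")
  res <- structure$residues
  hit <- match(res$auth_seq, offset_map$auth_seq)
  drop <- which(is.na(hit))
  if (length(drop)) {
    warning(length(drop), " residue(s) not covered by the offset map were dropped")
    structure <- structure_subset(structure, setdiff(seq_len(nrow(res)), drop))
    res <- structure$residues
    hit <- match(res$auth_seq, offset_map$auth_seq)
  }
  if (!nrow(res))
    stop2("offset map covers no residues", class = "sp_mapping_error")
  res$seq_index <- offset_map$target[hit]
  ord <- order(match(res$chain, unique(res$chain)), res$seq_index)
  structure$residues <- res
  structure <- structure_reorder(structure, ord)
  structure
}

# keep residues (global row ids), renumbering atom residue pointers
structure_subset <- function(structure, residue_ids) {
  residue_ids <- sort(unique(residue_ids))
  res <- structure$residues[residue_ids, , drop = FALSE]
  keep <- structure$atoms$residue %in% residue_ids
  at <- structure$atoms[keep, , drop = FALSE]
  at$residue <- match(at$residue, residue_ids)
  rownames(res) <- NULL; rownames(at) <- NULL
  out <- structure
  out$residues <- res
  out$atoms <- at
  out$chains <- unique(res$chain)
  out
}

structure_reorder <- function(structure, ord) {
  res <- structure$residues[ord, , drop = FALSE]
  at <- structure$atoms
  at$residue <- match(at$residue, ord)
  at <- at[order(at$residue), , drop = FALSE]
  rownames(res) <- NULL; rownames(at) <- NULL
  structure$residues <- res
  structure$atoms <- at
  structure
}

# single-chain view with global residue row ids recomputed
structure_chain <- function(structure, chain) {
  if (!chain %in% structure$chains)
    stop2("chain '", chain, "' not present; available: ",
          paste(structure$chains, collapse = ", "), class = "sp_chain_error")
  structure_subset(structure, which(structure$residues$chain == chain))
}
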