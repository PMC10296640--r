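# Per-residue conservation from an orthologue alignment: tree-weighted
# identity-to-query column scores, mapped onto structure residues.

#' Read an orthologue multiple sequence alignment
#'
#' Reads an aligned FASTA or Clustal file (via Biostrings) and validates
#' that the query sequence is present and all gapped lengths are equal.
#'
#' @param path Alignment file path.
#' @param query_id Identifier of the query (reference) sequence.
#' @param format `"fasta"` or `"clustal"` (`"auto"` sniffs the first line).
#' @return An `alignment` object: named character vector `seqs` of gapped
#'   sequences plus `query_id`.
#' @export
read_alignment <- function(path, query_id, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal" else "fasta"
  }
  aln <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) stop2("not a valid aligned ", format, " file: ",
                              conditionMessage(e), class = "sp_format_error"))
  seqs <- as.character(aln)
  if (length(unique(nchar(seqs))) != 1)
    stop2("ragged alignment: gapped sequence lengths differ",
          class = "sp_format_error")
  # tolerate description suffixes after the identifier
  ids <- sub("[ \t].*$", "", names(seqs))
  names(seqs) <- ids
  if (!query_id %in% ids)
    stop2("query '", query_id, "' not found in alignment",
          class = "sp_lookup_error")
  structure(list(seqs = seqs, query_id = query_id), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("<alignment> ", length(x$seqs), " sequences x ", nchar(x$seqs[1]),
      " columns, query: ", x$query_id, "\n", sep = "")
  invisible(x)
}

#' Guide-tree sequence weights
#'
#' Derives one weight per orthologue, proportional to the patristic
#' (branch-length) distance from the query leaf, normalised to sum to one
#' over the orthologues. More divergent orthologues therefore contribute
#' more to the conservation score: identity retained at large evolutionary
#' distance is stronger evidence of constraint. Without a tree (or with a
#' tree of zero total length) the weights are uniform.
#'
#' @param alignment An `alignment` object.
#' @param tree Optional [ape::read.tree()] phylo object (or a Newick file
#'   path) whose leaves cover the alignment identifiers; extra leaves are
#'   ignored with a warning.
#' @return Named numeric vector of weights over the orthologues (the query
#'   is excluded and receives no weight).
#' @export
sequence_weights <- function(alignment, tree = NULL) {
  orth <- setdiff(names(alignment$seqs), alignment$query_id)
  if (!length(orth)) stop2("alignment has no orthologues", class = "sp_input_error")
  uniform <- stats::setNames(rep(1 / length(orth), length(orth)), orth)
  if (is.null(tree)) return(uniform)
  if (is.character(tree)) tree <- ape::read.tree(tree)
  need <- c(alignment$query_id, orth)
  missing <- setdiff(need, tree$tip.label)
  if (length(missing))
    stop2("guide tree lacks leaves: ", paste(missing, collapse = ", "),
          class = "sp_lookup_error")
  extra <- setdiff(tree$tip.label, need)
  if (length(extra)) {
    warning(length(extra), " guide-tree leaf/leaves not in the alignment ignored")
    tree <- ape::drop.tip(tree, extra)
  }
  pd <- stats::cophenetic(tree)[alignment$query_id, orth]
  tot <- sum(pd)
  if (!is.finite(tot) || tot <= 0) {
    warning("guide tree has zero total distance to the query; using uniform weights")
    return(uniform)
  }
  pd / tot
}

#' Weighted conservation score profile
#'
#' For each alignment column where the query is not gapped, the weighted
#' conservation score (WCS) is the total weight of the orthologues carrying
#' the identical amino acid to the query in that column; orthologue gaps
#' count as mismatches, and the query's trivial self-match is excluded.
#' With weights summing to one the score lies in \[0, 1\] and, under
#' uniform weights, reduces to the fraction of orthologues matching the
#' query. The match function is pluggable so a substitution-similarity
#' scheme can be swapped in.
#'
#' @param alignment An `alignment`.
#' @param weights Named orthologue weights, as from [sequence_weights()].
#' @param match_fun Function `(orthologue_chars, query_char) -> 0/1 vector`;
#'   the default scores exact identity.
#' @return A `conservation_profile`: data frame with `position` (1-based
#'   ungapped query position), `wcs` and `coverage` (non-gap orthologue
#'   count per column).
#' @export
compute_wcs <- function(alignment, weights,
                        match_fun = function(chars, q) as.numeric(chars == q)) {
  seqs <- alignment$seqs
  orth <- setdiff(names(seqs), alignment$query_id)
  if (!all(orth %in% names(weights)))
    stop2("weights do not cover all orthologues", class = "sp_input_error")
  w <- weights[orth]
  qchars <- strsplit(seqs[[alignment$query_id]], "")[[1]]
  M <- do.call(rbind, strsplit(unname(seqs[orth]), ""))  # orthologues x columns
  keep <- which(!qchars %in% c("-", "."))
  gap <- M %in% c("-", ".")
  dim(gap) <- dim(M)
  wcs <- numeric(length(keep))
  cov <- integer(length(keep))
  for (k in seq_along(keep)) {
    col <- keep[k]
    sc <- match_fun(M[, col], qchars[col])
    sc[gap[, col]] <- 0
    wcs[k] <- sum(w * sc)
    cov[k] <- sum(!gap[, col])
  }
  structure(data.frame(position = seq_along(keep), wcs = wcs, coverage = cov),
            class = c("conservation_profile", "data.frame"))
}

#' Map a conservation profile onto structure residues
#'
#' Assigns each structure residue the WCS at its sequence index. Residues
#' without a profile entry receive the median of the mapped scores with a
#' warning; if more than `max_unmapped` of the residues are uncovered the
#' mapping is refused.
#'
#' @param profile A `conservation_profile`.
#' @param structure The `protein_structure` (after any renumbering).
#' @param max_unmapped Maximum tolerated unmapped fraction. Default 0.2.
#' @return Named numeric vector: WCS per residue sequence index.
#' @export
map_profile <- function(profile, structure, max_unmapped = 0.2) {
  idx <- structure$residues$seq_index
  hit <- match(idx, profile$position)
  frac <- mean(is.na(hit))
  if (frac > max_unmapped)
    stop2(sprintf("%.0f%% of residues have no conservation entry (limit %.0f%%)",
                  100 * frac, 100 * max_unmapped), class = "sp_mapping_error")
  out <- profile$wcs[hit]
  if (anyNA(out)) {
    warning(sum(is.na(out)), " residue(s) without profile entry assigned the ",
            "median mapped score")
    out[is.na(out)] <- stats::median(out, na.rm = TRUE)
  }
  stats::setNames(out, idx)
}

#' Write a conservation profile as TSV
#'
#' @param profile A `conservation_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
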