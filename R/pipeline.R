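# End-to-end orchestration: predicted-model mode (with module
# segmentation) and experimental-structure mode (whole chain as one
# module), plus result serialisation.

default_params <- function() {
  list(plddt_min = 70, pae_max = 5, min_module_size = 30, resolution = 0.8,
       max_patches = 3, p_cutoff = 1e-10, glycine_ca_proxy = FALSE,
       tol = 1e-8, max_iter = 1000, interface_cutoff = 6)
}

merge_params <- function(...) {
  p <- default_params()
  user <- list(...)
  unknown <- setdiff(names(user), names(p))
  if (length(unknown))
    stop2("unknown parameter(s): ", paste(unknown, collapse = ", "),
          class = "sp_input_error")
  p[names(user)] <- user
  p
}

#' Run the pipeline on a predicted (AlphaFold-style) model
#'
#' Executes the whole workflow: (i) segmentation of autonomous structural
#' modules from the inverse-PAE graph; then per module (ii) Delaunay
#' tessellation and side-chain accessibility, (iii) per-residue weighted
#' conservation from the orthologue alignment, (iv) TAC graph
#' construction, (v) eigenvector centrality, (vi) minimum-variance
#' clustering and connected-patch extraction, (vii) patch scoring and
#' (viii) iteration for further patches. Modules whose geometry fails are
#' skipped with a recorded reason; the other modules are still reported.
#'
#' @param model Path to the model (PDB or mmCIF) carrying pLDDT in the
#'   B-factor field.
#' @param pae Path to the PAE JSON (required in this mode).
#' @param alignment Path to the orthologue alignment (FASTA or Clustal)
#'   containing the query.
#' @param query_id Identifier of the query sequence in the alignment.
#' @param tree Optional Newick guide-tree path (uniform weights without).
#' @param chain Chain to analyse if the model has several.
#' @param ... Parameter overrides: `plddt_min` (70), `pae_max` (5 A),
#'   `min_module_size` (30), `resolution` (0.8), `max_patches` (3),
#'   `p_cutoff` (1e-10), `glycine_ca_proxy` (FALSE), `tol`, `max_iter`.
#' @return An `analysis_result`.
#' @export
run_alphafold_mode <- function(model, pae, alignment, query_id,
                               tree = NULL, chain = NULL, ...) {
  params <- merge_params(...)
  if (is.null(pae) || !file.exists(pae))
    stop2("PAE file is required for predicted-model analysis; for ",
          "experimental structures without a PAE use run_pdb_mode()",
          class = "sp_input_error")
  st <- read_structure(model)
  if (st$source_kind != "alphafold-model")
    stop2("model carries no per-residue pLDDT; use run_pdb_mode() for ",
          "experimental structures", class = "sp_input_error")
  st <- pick_chain(st, chain)
  paem <- read_pae(pae)
  consmap <- conservation_from_files(alignment, query_id, tree, st)

  g <- build_pae_graph(st, paem, params$plddt_min, params$pae_max)
  part <- detect_communities(g, resolution = params$resolution)
  modules <- filter_modules(part, st, paem, params$min_module_size)
  status <- if (length(modules)) "ok" else
    "no structural module of sufficient size; nothing to analyse"

  results <- lapply(modules, function(m)
    process_module(st, m, consmap, params))
  new_analysis_result(results, params,
                      inputs = list(model = model, pae = pae,
                                    alignment = alignment, tree = tree,
                                    query_id = query_id, mode = "alphafold"),
                      status = status)
}

#' Run the pipeline on an experimental structure
#'
#' Module segmentation needs a PAE matrix and is skipped: the selected
#' chain is treated as one structural module and all remaining steps run
#' unchanged. An optional offset map renumbers structure residues to the
#' alignment (e.g. UniProt) numbering first.
#'
#' @param structure Path to the PDB/mmCIF file.
#' @param chain Chain identifier to analyse.
#' @param alignment,query_id,tree As in [run_alphafold_mode()].
#' @param offset_map Optional path to a two-column TSV (author residue
#'   number, target position) or a data frame, see [read_offset_map()].
#' @param ... Parameter overrides, as in [run_alphafold_mode()].
#' @return An `analysis_result` with a single module.
#' @export
run_pdb_mode <- function(structure, chain, alignment, query_id, tree = NULL,
                         offset_map = NULL, ...) {
  params <- merge_params(...)
  st <- read_structure(structure)
  st <- structure_chain(st, chain)
  if (!is.null(offset_map)) {
    if (is.character(offset_map)) offset_map <- read_offset_map(offset_map)
    st <- map_positions(st, offset_map)
  }
  consmap <- conservation_from_files(alignment, query_id, tree, st)
  m <- structure(list(residues = st$residues$seq_index,
                      mean_pae = NA_real_,
                      mean_plddt = if (anyNA(st$residues$plddt)) NA_real_
                                   else mean(st$residues$plddt),
                      rank = 1L), class = "structural_module")
  results <- list(process_module(st, m, consmap, params))
  new_analysis_result(results, params,
                      inputs = list(model = structure, chain = chain,
                                    alignment = alignment, tree = tree,
                                    query_id = query_id, mode = "pdb"),
                      status = "ok")
}

conservation_from_files <- function(alignment, query_id, tree, st) {
  aln <- read_alignment(alignment, query_id = query_id)
  wts <- sequence_weights(aln, tree)
  prof <- compute_wcs(aln, wts)
  map_profile(prof, st)
}

process_module <- function(st, module, consmap, params) {
  rows <- which(st$residues$seq_index %in% module$residues)
  sub <- structure_subset(st, rows)
  geom <- tryCatch(surface_model(sub, params$glycine_ca_proxy),
                   surfpatch_error = function(e)
                     structure(list(msg = conditionMessage(e)), class = "sp_fail"))
  base <- list(rank = module$rank, residues = module$residues,
               mean_pae = module$mean_pae, mean_plddt = module$mean_plddt)
  if (inherits(geom, "sp_fail"))
    return(c(base, list(status = paste0("geometry failed: ", geom$msg),
                        patches = list())))
  acc <- geom$accessible_residues
  tacp <- tryCatch({
    tac <- build_tac_graph(acc, geom$adjacency, consmap)
    patches <- iterate_patches(tac, max_patches = params$max_patches,
                               p_cutoff = params$p_cutoff, tol = params$tol,
                               max_iter = params$max_iter)
    list(tac = tac, patches = patches)
  }, surfpatch_error = function(e)
    structure(list(msg = conditionMessage(e)), class = "sp_fail"))
  if (inherits(tacp, "sp_fail"))
    return(c(base, list(status = paste0("patch extraction failed: ", tacp$msg),
                        patches = list())))
  patches <- tacp$patches
  cent1 <- if (length(patches)) patches[[1]]$centrality else NULL
  ridx <- sub$residues$seq_index
  tab <- data.frame(
    residue = ridx,
    resname = sub$residues$resname,
    plddt = sub$residues$plddt,
    wcs = unname(consmap[as.character(ridx)]),
    accessible = ridx %in% acc,
    centrality = if (is.null(cent1)) NA_real_
                 else unname(cent1[as.character(ridx)]))
  c(base, list(status = "ok", accessible = acc,
               n_adjacency = nrow(geom$adjacency),
               residue_table = tab, patches = patches))
}

new_analysis_result <- function(modules, params, inputs, status) {
  structure(list(
    modules = modules,
    params = params,
    provenance = list(
      inputs = inputs,
      tool = "surfpatch",
      version = as.character(utils::packageVersion("surfpatch")),
      generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    status = status
  ), class = "analysis_result")
}

#' @export
print.analysis_result <- function(x, ...) {
  cat("<analysis_result> ", length(x$modules), " module(s); status: ",
      x$status, "\n", sep = "")
  for (m in x$modules) {
    cat(sprintf("  module %d: %d residues, status %s, %d patch(es)\n",
                m$rank, length(m$residues), m$status, length(m$patches)))
    for (p in m$patches)
      cat(sprintf("    patch %d: %d residues, absolute %.3f, relative %.3f, p = %.3g\n",
                  p$iteration, length(p$residues), p$absolute, p$relative,
                  p$p_value))
  }
  invisible(x)
}

#' Serialise an analysis result as JSON
#'
#' Writes the module definitions, per-residue tables and patch metrics as
#' JSON. The output is byte-stable for identical inputs and parameters
#' apart from the `generated_at` provenance timestamp.
#'
#' @param result An `analysis_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(result, path) {
  mods <- lapply(result$modules, function(m) {
    out <- list(id = m$rank, residues = m$residues,
                mean_plddt = m$mean_plddt, mean_pae = m$mean_pae,
                status = m$status)
    if (!is.null(m$residue_table)) out$residue_table <- m$residue_table
    out$patches <- lapply(m$patches, function(p)
      list(iteration = p$iteration, residues = p$residues, seed = p$seed,
           absolute = p$absolute, relative = p$relative,
           p_value = p$p_value, significant = p$significant))
    out
  })
  obj <- list(modules = mods, params = result$params,
              provenance = result$provenance, status = result$status)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}

#' Export module definitions as TSV
#'
#' One row per module: id, chain, residue indices as comma-joined runs.
#'
#' @param result An `analysis_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_module_tsv <- function(result, path) {
  runs <- function(v) {
    if (!length(v)) return("")
    d <- cumsum(c(1L, diff(v) != 1L))
    paste(tapply(v, d, function(r)
      if (length(r) > 1) paste0(r[1], "-", r[length(r)]) else as.character(r)),
      collapse = ",")
  }
  df <- do.call(rbind, lapply(result$modules, function(m)
    data.frame(module = m$rank, n_residues = length(m$residues),
               residues = runs(m$residues), mean_pae = m$mean_pae,
               mean_plddt = m$mean_plddt, status = m$status)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export patches as TSV
#'
#' One row per extracted patch: module, iteration, residues, metrics.
#'
#' @param result An `analysis_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patch_tsv <- function(result, path) {
  rows <- list()
  for (m in result$modules)
    for (p in m$patches)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m$rank, iteration = p$iteration,
        residues = paste(p$residues, collapse = ","),
        absolute = p$absolute, relative = p$relative, p_value = p$p_value,
        significant = p$significant)
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = integer(0), iteration = integer(0),
               residues = character(0), absolute = numeric(0),
               relative = numeric(0), p_value = numeric(0),
               significant = logical(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pick_chain <- function(st, chain) {
  if (!is.null(chain)) return(structure_chain(st, chain))
  if (length(st$chains) == 1) return(st)
  stop2("model has several chains (", paste(st$chains, collapse = ", "),
        "); pick one with `chain`", class = "sp_chain_error")
}
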