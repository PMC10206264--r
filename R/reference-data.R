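#' Path to a packaged data file
#'
#' @param file File name under the package's `extdata/`.
#' @return Absolute path.
#' @export
bindsight_extdata <- function(file) {
  p <- system.file("extdata", file, package = "bindsight", mustWork = FALSE)
  if (!nzchar(p)) abort(paste0("no packaged data file '", file, "'"))
  p
}

#' Reported abemaciclib/CDK6 MM/GBSA energy components
#'
#' The published complex/receptor/ligand/delta component table for the
#' abemaciclib/CDK6 system, shipped as reference input for the energy
#' assembly and accounting operations.
#'
#' @return Tibble with `term`, `complex`, `receptor`, `ligand`, `delta`
#'   (kcal/mol).
#' @export
reference_energy_components <- function() {
  readr::read_tsv(bindsight_extdata("abemaciclib_cdk6_energy.tsv"),
                  comment = "#", show_col_types = FALSE)
}

#' Reported abemaciclib/CDK6 per-residue decomposition
#'
#' @return Tibble with `residue` and the component/subtotal columns
#'   (kcal/mol).
#' @export
reference_residue_decomposition <- function() {
  readr::read_tsv(bindsight_extdata("abemaciclib_cdk6_residue_decomposition.tsv"),
                  comment = "#", show_col_types = FALSE)
}

#' Packaged one-region ensemble docking score table
#'
#' Aggregated (minimum over cluster receptors) docking scores for the
#' one-region modification library, keyed to the pseudo-member `"ensemble"`.
#' Entries never printed in the source study carry synthetic placeholder
#' scores (see the file header).
#'
#' @return Scorer function from [load_score_table()].
#' @export
reference_one_region_scorer <- function() {
  load_score_table(bindsight_extdata("one_region_scores.tsv"))
}

#' Load a design library (scaffold + region group libraries) from YAML
#'
#' The file holds the scaffold template with its base groups, the one-region
#' modification libraries, the reduced combination libraries and named variant
#' edits. `path = NULL` loads the packaged abemaciclib-analogue library.
#'
#' @param path YAML path, or `NULL` for the packaged default.
#' @return List with `scaffold` ([scaffold()]), `one_region` and `combination`
#'   (named lists of [group_library()]), `variants` (list of edits).
#' @export
read_design_library <- function(path = NULL) {
  path <- path %||% bindsight_extdata("design_library.yaml")
  if (!file.exists(path)) abort(paste0("design library not found: ", path))
  y <- yaml::read_yaml(path)
  base <- vapply(y$scaffold$base, function(x) if (is.null(x)) "" else x, "")
  sc <- scaffold(y$scaffold$template, base,
                 description = y$scaffold$description %||% "")
  to_libs <- function(section) {
    out <- list()
    for (r in names(section)) {
      ent <- purrr::map_dfr(section[[r]], function(e) {
        tibble(label = e$label,
               smiles = e$smiles %||% "",
               description = e$description %||% "")
      })
      out[[r]] <- group_library(r, ent)
    }
    out
  }
  list(scaffold = sc,
       one_region = to_libs(y$one_region),
       combination = to_libs(y$combination),
       variants = y$variants %||% list())
}
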