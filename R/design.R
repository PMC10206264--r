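#' R-group library for one design region
#'
#' @param region Region id, e.g. `"R1"`.
#' @param entries Tibble (or data frame) with columns `label` (unique, e.g.
#'   `"R1a"`), `smiles` (fragment spliced at the region's attachment point;
#'   an empty string means hydrogen), `description`.
#' @return A `bs_group_library`.
#' @export
group_library <- function(region, entries) {
  entries <- as_tibble(entries)
  stopifnot(all(c("label", "smiles", "description") %in% names(entries)))
  if (anyDuplicated(entries$label)) abort("library labels must be unique")
  structure(list(region = region, entries = entries), class = "bs_group_library")
}

#' @export
print.bs_group_library <- function(x, ...) {
  cat("<bs_group_library> region ", x$region, ", ", nrow(x$entries),
      " entries\n", sep = "")
  print(x$entries)
  invisible(x)
}

#' Design scaffold with four numbered attachment points
#'
#' The scaffold SMILES carries one `{R1}` ... `{R4}` token per region. A
#' fragment replaces its token; an empty (hydrogen) fragment removes the
#' enclosing parenthesized branch `({Ri})` when the token is parenthesized.
#' Fragments must use ring-closure digits >= 4 to avoid colliding with the
#' scaffold's own ring numbering.
#'
#' @param smiles_template Template SMILES with the four tokens.
#' @param base_groups Named character vector: the reference compound's
#'   fragment per region (`R1`..`R4`).
#' @param description Free-text note on the invariant core.
#' @return A `bs_scaffold`.
#' @export
scaffold <- function(smiles_template, base_groups, description = "") {
  for (r in c("R1", "R2", "R3", "R4")) {
    hits <- gregexpr(paste0("\\{", r, "\\}"), smiles_template)[[1]]
    if (length(hits[hits > 0]) != 1) {
      abort(paste0("template must contain exactly one {", r, "} token"))
    }
  }
  stopifnot(all(c("R1", "R2", "R3", "R4") %in% names(base_groups)))
  structure(list(smiles_template = smiles_template,
                 base_groups = base_groups,
                 description = description),
            class = "bs_scaffold")
}

#' Assemble and canonicalize a compound SMILES from region fragments
#'
#' @param scaffold A [scaffold()].
#' @param fragments Named character vector/list of fragments for `R1`..`R4`;
#'   missing regions fall back to the scaffold's base groups.
#' @return List with `smiles_raw` (spliced template) and `smiles` (canonical,
#'   via Open Babel). Errors if the assembled SMILES is invalid.
#' @export
assemble_smiles <- function(scaffold, fragments = list()) {
  frags <- scaffold$base_groups
  for (r in names(fragments)) frags[[r]] <- fragments[[r]]
  smi <- scaffold$smiles_template
  for (r in c("R1", "R2", "R3", "R4")) {
    frag <- frags[[r]]
    if (is.null(frag) || is.na(frag)) frag <- ""
    if (frag %in% c("", "[H]", "H")) {
      smi <- sub(paste0("\\(\\{", r, "\\}\\)"), "", smi)
      smi <- sub(paste0("\\{", r, "\\}"), "", smi)
    } else {
      smi <- sub(paste0("\\{", r, "\\}"), frag, smi, fixed = FALSE)
    }
  }
  list(smiles_raw = smi, smiles = canonical_smiles(smi))
}

#' Canonicalize a SMILES string
#'
#' Round-trips through Open Babel (via \pkg{ChemmineOB}); errors on invalid
#' input.
#'
#' @param smiles SMILES string.
#' @return Canonical SMILES string.
#' @export
canonical_smiles <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n")),
    error = function(e) "")
  out <- strsplit(trimws(out), "[ \t\n]")[[1]][1]
  if (is.na(out) || !nzchar(out)) {
    abort(paste0("invalid SMILES: ", smiles))
  }
  out
}

#' Count heavy (non-hydrogen) atoms in a SMILES string
#'
#' @param smiles SMILES string.
#' @return Integer heavy-atom count.
#' @export
heavy_atom_count <- function(smiles) {
  s <- gsub("\\[[^]]*H[^]]*\\]", "[X]", smiles)  # bracket atoms count once
  toks <- gregexpr("Cl|Br|Si|Se|\\[[^]]*\\]|[BCNOPSFI]|[bcnops]", s)[[1]]
  sum(toks > 0)
}

#' Compound naming for cross-combinations
#'
#' Combination compounds are named `"C"` followed by the 1-based group index
#' chosen for R1, R2, R3, R4 in order (e.g. `C1333`); a variant tag is
#' appended after a dash (`C2213-A`).
#'
#' @param choice Integer vector of four 1-based group indices.
#' @param variant_tag Optional tag, e.g. `"A"`.
#' @return Compound name string.
#' @export
compound_name <- function(choice, variant_tag = NULL) {
  stopifnot(length(choice) == 4)
  nm <- paste0("C", paste0(choice, collapse = ""))
  if (!is.null(variant_tag) && nzchar(variant_tag)) {
    nm <- paste0(nm, "-", variant_tag)
  }
  nm
}

#' Parse a combination compound name back to its group choice
#'
#' @param name Name like `"C1333"` or `"C2213-A"`.
#' @return List with `choice` (integer 4-vector) and `variant_tag` (or `NA`).
#' @export
parse_compound_name <- function(name) {
  m <- regmatches(name, regexec("^C([1-9])([1-9])([1-9])([1-9])(?:-(.+))?$", name))[[1]]
  if (!length(m)) abort(paste0("not a combination compound name: ", name))
  list(choice = as.integer(m[2:5]),
       variant_tag = if (nzchar(m[6])) m[6] else NA_character_)
}

#' Enumerate one-region modification compounds
#'
#' For each region, substitutes each library entry while holding the other
#' three regions at the base compound's groups. Entries identical to the base
#' group of their region are dropped (they would reproduce the base compound).
#'
#' @param scaffold A [scaffold()].
#' @param libraries List of [group_library()] objects (one per region).
#' @return Tibble with `name` (the entry label), `region`, `label`,
#'   `description`, `smiles_raw`, `smiles` (canonical).
#' @export
enumerate_one_region <- function(scaffold, libraries) {
  rows <- list()
  for (lib in libraries) {
    region <- lib$region
    for (k in seq_len(nrow(lib$entries))) {
      e <- lib$entries[k, ]
      if (identical(e$smiles, unname(scaffold$base_groups[[region]]))) next
      asm <- tryCatch(
        assemble_smiles(scaffold, setNames(list(e$smiles), region)),
        error = function(err) {
          abort(paste0("library entry ", e$label, ": ", conditionMessage(err)))
        })
      rows[[length(rows) + 1L]] <- tibble(
        name = e$label, region = region, label = e$label,
        description = e$description,
        smiles_raw = asm$smiles_raw, smiles = asm$smiles)
    }
  }
  bind_rows(rows)
}

#' Select the top groups per region from scored one-region compounds
#'
#' Groups are ranked per region by their compound's aggregate score, ascending
#' (more negative binds better); ties break by library order. The base group
#' competes with score `base_score` and keeps its fragment if it ranks.
#'
#' @param scored One-region tibble (from [enumerate_one_region()]) with an
#'   `aggregate_score` column (kcal/mol); every row must be scored.
#' @param libraries The original [group_library()] list (defines tie order).
#' @param scaffold The [scaffold()] (supplies the base groups).
#' @param base_score Aggregate score of the base compound.
#' @param per_region Number of groups kept per region.
#' @return List of reduced [group_library()] objects, entries ordered by rank
#'   (index 1 = best).
#' @export
select_top_groups <- function(scored, libraries, scaffold, base_score,
                              per_region = 3L) {
  if (anyNA(scored$aggregate_score)) abort("every compound must be scored")
  out <- list()
  for (lib in libraries) {
    region <- lib$region
    cand <- lib$entries |>
      mutate(lib_order = row_number()) |>
      left_join(scored |> filter(.data$region == !!region) |>
                  select("label", "aggregate_score"),
                by = "label") |>
      filter(!is.na(.data$aggregate_score))  # base-duplicate entries fall out
    cand <- bind_rows(
      cand,
      tibble(label = paste0(region, "-base"),
             smiles = unname(scaffold$base_groups[[region]]),
             description = "base compound group",
             lib_order = 0L, aggregate_score = base_score))
    keep <- cand |>
      arrange(.data$aggregate_score, .data$lib_order) |>
      head(per_region)
    out[[region]] <- group_library(region, keep |>
                                     select("label", "smiles", "description"))
  }
  out
}

#' Cross-combine region groups into the full compound matrix
#'
#' Full Cartesian product over the reduced libraries, named by the 1-based
#' group indices (`C` + R1 index + R2 + R3 + R4) and assembled/canonicalized.
#'
#' @param scaffold A [scaffold()].
#' @param reduced Named list of reduced [group_library()] objects for
#'   `R1`..`R4` (entry order defines the group indices).
#' @return Tibble with `name`, `r1`..`r4` (labels), `choice` (list-column),
#'   `smiles_raw`, `smiles`.
#' @export
combine_regions <- function(scaffold, reduced) {
  regions <- c("R1", "R2", "R3", "R4")
  stopifnot(all(regions %in% names(reduced)))
  sizes <- vapply(reduced[regions], function(l) nrow(l$entries), 0L)
  if (any(sizes == 0)) abort("every region library must be non-empty")
  grid <- expand.grid(i4 = seq_len(sizes[4]), i3 = seq_len(sizes[3]),
                      i2 = seq_len(sizes[2]), i1 = seq_len(sizes[1]))
  grid <- grid[order(grid$i1, grid$i2, grid$i3, grid$i4), ]
  rows <- purrr::pmap(grid, function(i4, i3, i2, i1) {
    choice <- c(i1, i2, i3, i4)
    frags <- purrr::map2(reduced[regions], choice,
                         function(l, i) l$entries$smiles[i])
    names(frags) <- regions
    asm <- assemble_smiles(scaffold, frags)
    tibble(name = compound_name(choice),
           r1 = reduced$R1$entries$label[i1],
           r2 = reduced$R2$entries$label[i2],
           r3 = reduced$R3$entries$label[i3],
           r4 = reduced$R4$entries$label[i4],
           choice = list(choice),
           smiles_raw = asm$smiles_raw, smiles = asm$smiles)
  })
  out <- bind_rows(rows)
  if (anyDuplicated(out$name)) abort("internal error: compound name collision")
  out
}

#' Apply a named structural edit, producing a tagged variant
#'
#' The edit is a literal SMILES substring replacement (e.g. deleting the
#' methylene linker between two ring systems) applied once to the compound's
#' raw assembled SMILES. The pattern must match; re-applying the same edit to
#' the variant errors because the pattern is consumed.
#'
#' @param compound One-row tibble with `name`, `smiles_raw` (e.g. a row of
#'   [combine_regions()] output).
#' @param variant List with `tag` (e.g. `"A"`), `pattern`, `replacement`
#'   (literal strings).
#' @return The edited one-row tibble with updated `name`, `smiles_raw`,
#'   `smiles` and a `variant_tag` column.
#' @export
apply_variant <- function(compound, variant) {
  stopifnot(all(c("tag", "pattern", "replacement") %in% names(variant)))
  raw <- compound$smiles_raw
  if (!grepl(variant$pattern, raw, fixed = TRUE)) {
    abort(paste0("edit pattern not found in ", compound$name, ": ",
                 variant$pattern))
  }
  new_raw <- sub(variant$pattern, variant$replacement, raw, fixed = TRUE)
  out <- compound
  out$smiles_raw <- new_raw
  out$smiles <- canonical_smiles(new_raw)
  out$variant_tag <- variant$tag
  out$name <- paste0(compound$name, "-", variant$tag)
  out
}
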