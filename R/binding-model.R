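#' Classify residue-ligand interactions into a binding-model report
#'
#' Fuses per-residue energy contributions, hydrogen-bond occupancies and
#' (optionally) geometric contact monitors into one annotated table, the basis
#' for region-directed design. Classes, in precedence order:
#'
#' * `hydrogen-bond`: the residue hosts an H-bond with occupancy at or above
#'   `stable_occupancy` (default 50%).
#' * `unstable-hydrogen-bond`: occupancy in `[unstable_floor, stable_occupancy)`
#'   (default 10-50%).
#' * `unfavorable`: subtotal at or above `+key_threshold`.
#' * `pi-alkyl`: favorable (subtotal at or below `-key_threshold`) with a mean
#'   heavy-atom contact distance at or below `pi_alkyl_distance` (default
#'   4.5 A) and no hydrogen bond.
#'
#' @param contribs Per-residue tibble from [decompose_per_residue()].
#' @param hbonds H-bond tibble from [detect_hbonds()].
#' @param contacts Optional tibble of per-residue mean contact distances with
#'   columns `residue_index`, `mean_distance` (A).
#' @param thresholds Named list overriding `stable_occupancy`,
#'   `unstable_floor`, `pi_alkyl_distance`, `key_threshold`.
#' @return A `bs_binding_model`: `key_residues` (contributions filtered at the
#'   threshold), `stable_hbonds`, `residue_classes` tibble and the thresholds
#'   used. Pure function of its inputs.
#' @export
classify_interactions <- function(contribs, hbonds, contacts = NULL,
                                  thresholds = list()) {
  th <- utils::modifyList(list(stable_occupancy = 50, unstable_floor = 10,
                               pi_alkyl_distance = 4.5, key_threshold = 0.5),
                          thresholds)
  # max occupancy of any H-bond hosted by each receptor residue
  res_occ <- tibble(residue_index = integer(), occupancy = double())
  if (nrow(hbonds)) {
    lab_idx <- function(lab) as.integer(gsub("^[A-Za-z]+|@.*$", "", lab))
    res_occ <- bind_rows(
      tibble(residue_index = lab_idx(hbonds$donor), occupancy = hbonds$occupancy),
      tibble(residue_index = lab_idx(hbonds$acceptor), occupancy = hbonds$occupancy)) |>
      group_by(.data$residue_index) |>
      summarise(occupancy = max(.data$occupancy), .groups = "drop")
  }
  rec <- contribs |> filter(.data$residue_name != "LIG")
  rec <- left_join(rec, res_occ, by = "residue_index")
  if (!is.null(contacts)) {
    rec <- left_join(rec, contacts, by = "residue_index")
  } else {
    rec$mean_distance <- NA_real_
  }
  rec <- rec |>
    mutate(occupancy = tidyr::replace_na(.data$occupancy, 0),
           class = dplyr::case_when(
             .data$occupancy >= th$stable_occupancy ~ "hydrogen-bond",
             .data$occupancy >= th$unstable_floor ~ "unstable-hydrogen-bond",
             .data$d_subtotal >= th$key_threshold ~ "unfavorable",
             .data$d_subtotal <= -th$key_threshold &
               !is.na(.data$mean_distance) &
               .data$mean_distance <= th$pi_alkyl_distance ~ "pi-alkyl",
             TRUE ~ NA_character_))
  structure(list(
    key_residues = rec |> filter(abs(.data$d_subtotal) >= th$key_threshold),
    stable_hbonds = hbonds |> filter(.data$occupancy >= th$stable_occupancy),
    residue_classes = rec |> filter(!is.na(.data$class)) |>
      select("chain_id", "residue_index", "residue_name", "d_subtotal",
             "occupancy", "mean_distance", "class"),
    thresholds = th), class = "bs_binding_model")
}

#' @export
print.bs_binding_model <- function(x, ...) {
  cat("<bs_binding_model> ", nrow(x$key_residues), " key residues, ",
      nrow(x$stable_hbonds), " stable H-bonds\n", sep = "")
  print(x$residue_classes)
  invisible(x)
}

#' Assign ligand atoms to design regions
#'
#' Validates a user-supplied partition of the ligand into modification regions
#' (classically R1-R4): regions must be disjoint subsets of the ligand;
#' unassigned ligand atoms are listed as linker.
#'
#' @param structure A complex [bs_structure()] with a `"ligand"` group.
#' @param region_spec Named list of ligand atom index vectors, e.g.
#'   `list(R1 = c(...), ..., R4 = c(...))`. An optional `annotations`
#'   character vector (same names) is carried through.
#' @param annotations Optional named character vector of per-region notes.
#' @return A `bs_region_map`: `regions` (named list), `linker` (atom indices),
#'   `annotations`.
#' @export
assign_regions <- function(structure, region_spec, annotations = NULL) {
  lig <- atom_group(structure, "ligand")
  regions <- lapply(region_spec, as.integer)
  all_idx <- unlist(regions, use.names = FALSE)
  if (anyDuplicated(all_idx)) {
    dup <- unique(all_idx[duplicated(all_idx)])
    abort(paste0("regions overlap on atom(s): ", paste(dup, collapse = ", ")))
  }
  if (!all(all_idx %in% lig)) {
    abort("region atoms must belong to the ligand group")
  }
  structure(list(regions = regions,
                 linker = setdiff(lig, all_idx),
                 annotations = annotations),
            class = "bs_region_map")
}

#' @export
print.bs_region_map <- function(x, ...) {
  cat("<bs_region_map>\n")
  for (r in names(x$regions)) {
    cat("  ", r, ": ", length(x$regions[[r]]), " atoms",
        if (!is.null(x$annotations) && r %in% names(x$annotations)) {
          paste0(" (", x$annotations[[r]], ")")
        } else "", "\n", sep = "")
  }
  cat("  linker: ", length(x$linker), " atoms\n", sep = "")
  invisible(x)
}
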