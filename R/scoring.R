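#' Score one compound against a receptor ensemble
#'
#' Calls the scorer for every ensemble member and aggregates by the minimum
#' (the best, most negative score across receptor conformations). Members for
#' which the scorer declares failure (returns `NA`) are recorded; if every
#' member fails the call errors.
#'
#' @param compound One-row tibble with at least a `name` column (and whatever
#'   the scorer needs, e.g. `smiles` or a pose).
#' @param ensemble A `bs_ensemble` from [receptor_ensemble()], or any list
#'   with named `members`.
#' @param scorer Function `(compound, member_label, member_structure) ->`
#'   kcal/mol or `NA` for a declared failure.
#' @return One-row tibble: `name`, one `score_<label>` column per member,
#'   `aggregate` (min over successful members), `failed_members`.
#' @export
score_compound <- function(compound, ensemble, scorer) {
  labels <- names(ensemble$members)
  per <- vapply(labels, function(lb) {
    as.numeric(scorer(compound, lb, ensemble$members[[lb]]))
  }, 0)
  if (all(is.na(per))) {
    abort(paste0("scorer failed on every ensemble member for ", compound$name))
  }
  out <- tibble(name = compound$name)
  for (lb in labels) out[[paste0("score_", lb)]] <- unname(per[lb])
  out$aggregate <- min(per, na.rm = TRUE)
  out$failed_members <- paste(labels[is.na(per)], collapse = ",")
  out
}

#' Score a compound table against an ensemble
#'
#' @param compounds Tibble of compounds (one per row).
#' @param ensemble A receptor ensemble.
#' @param scorer Scorer function, see [score_compound()].
#' @return Tibble of [score_compound()] rows.
#' @export
score_compounds <- function(compounds, ensemble, scorer) {
  purrr::map_dfr(seq_len(nrow(compounds)), function(i) {
    score_compound(compounds[i, ], ensemble, scorer)
  })
}

#' Deterministic single-point surrogate scorer
#'
#' Physics-flavoured stand-in for an external docking engine: intermolecular
#' Lennard-Jones plus Coulomb electrostatics under a distance-dependent
#' dielectric `eps(r) = 4r`, plus the surface-tension-scaled buried surface
#' area. Scores a supplied pose only; there is no conformational search. A
#' clash (any intermolecular distance < 0.5 A) is a declared failure (`NA`),
#' not an error.
#'
#' @param pose A complex [bs_structure()] carrying the ligand pose in its
#'   `"ligand"` group (receptor coordinates are the member's).
#' @param params A [gb_params()] (surface tension and probe radius are used).
#' @return Score in kcal/mol (more negative = better), or `NA` on clash.
#' @export
surrogate_score <- function(pose, params = gb_params()) {
  xyz <- coords(pose)
  rec <- atom_group(pose, "receptor"); lig <- atom_group(pose, "ligand")
  at <- pose$atoms
  dx <- outer(xyz[rec, 1], xyz[lig, 1], "-")
  dy <- outer(xyz[rec, 2], xyz[lig, 2], "-")
  dz <- outer(xyz[rec, 3], xyz[lig, 3], "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(r < 0.5)) return(NA_real_)
  sig <- outer(at$lj_sigma[rec], at$lj_sigma[lig], "+") / 2
  eps <- sqrt(outer(at$lj_epsilon[rec], at$lj_epsilon[lig]))
  sr6 <- (sig / r)^6
  e_vdw <- sum(4 * eps * (sr6^2 - sr6))
  # distance-dependent dielectric eps(r) = 4r
  e_ele <- .const$coulomb * sum(outer(at$charge[rec], at$charge[lig]) / (4 * r^2))
  d_sasa <- sasa(pose, xyz, NULL, params$probe_radius, params$sasa_points)$total -
    sasa(pose, xyz, rec, params$probe_radius, params$sasa_points)$total -
    sasa(pose, xyz, lig, params$probe_radius, params$sasa_points)$total
  e_vdw + e_ele + params$surface_tension * d_sasa
}

#' Build a pose-based surrogate scorer for [score_compound()]
#'
#' The returned scorer places the compound's pose (a ligand-bearing
#' [bs_structure()], supplied per compound in a `pose` list-column or shared
#' via `default_pose`) into each ensemble member's receptor and evaluates
#' [surrogate_score()].
#'
#' @param default_pose Complex structure used when a compound carries no pose.
#' @param params A [gb_params()].
#' @return Scorer function.
#' @export
surrogate_scorer <- function(default_pose = NULL, params = gb_params()) {
  function(compound, member_label, member_structure) {
    pose <- if ("pose" %in% names(compound)) compound$pose[[1]] else default_pose
    if (is.null(pose)) return(NA_real_)
    lig <- pose$atoms[atom_group(pose, "ligand"), ]
    combined <- .combine_receptor_ligand(member_structure, lig)
    surrogate_score(combined, params)
  }
}

# Stitch a receptor-only structure and a ligand atom table (with coordinates)
# into one complex structure.
.combine_receptor_ligand <- function(receptor_structure, ligand_atoms) {
  rec_at <- receptor_structure$atoms[atom_group(receptor_structure, "receptor"), ]
  at <- bind_rows(rec_at, ligand_atoms)
  at$serial <- seq_len(nrow(at))
  nr <- nrow(rec_at)
  bs_structure(at, groups = list(receptor = seq_len(nr),
                                 ligand = nr + seq_len(nrow(ligand_atoms))))
}

#' Load a tabular scorer from a (compound, member, score) TSV
#'
#' The table answers exact `(compound, member)` pairs; anything else is a
#' declared failure. Duplicate pairs and malformed rows error with the line
#' number.
#'
#' @param path TSV with header columns `compound`, `member`, `score`.
#' @return Scorer function for [score_compound()] with the score table
#'   attached as attribute `"table"`.
#' @export
load_score_table <- function(path) {
  if (!file.exists(path)) abort(paste0("score table not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("compound", "member", "score") %in% names(tab))) {
    abort("score table needs columns: compound, member, score")
  }
  bad <- which(is.na(tab$score) | is.na(tab$compound) | is.na(tab$member))
  if (length(bad)) {
    abort(paste0("malformed score-table row at line ", bad[1] + 1))
  }
  key <- paste(tab$compound, tab$member, sep = "\r")
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (compound, member) pair at line ",
                 which(duplicated(key))[1] + 1))
  }
  lookup <- setNames(tab$score, key)
  scorer <- function(compound, member_label, member_structure) {
    v <- lookup[paste(compound$name, member_label, sep = "\r")]
    if (is.na(v)) NA_real_ else unname(v)
  }
  attr(scorer, "table") <- tab
  scorer
}

#' Rank scored compounds and shortlist at a threshold
#'
#' Ascending sort by aggregate score (ties broken by name, lexically);
#' compounds at or below the threshold form the shortlist.
#'
#' @param records Tibble with `name` and `aggregate` columns.
#' @param threshold Shortlist cutoff, kcal/mol (default -10.00).
#' @return The ranked tibble with `rank` and logical `shortlisted` columns.
#' @export
rank_and_shortlist <- function(records, threshold = -10.0) {
  if (!nrow(records)) {
    return(dplyr::mutate(records, rank = integer(), shortlisted = logical()))
  }
  records |>
    arrange(.data$aggregate, .data$name) |>
    mutate(rank = row_number(),
           shortlisted = .data$aggregate <= threshold)
}
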