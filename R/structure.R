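#' Molecular structure container
#'
#' A `bs_structure` bundles a per-atom parameter table, an optional bond list
#' and named atom groups (at minimum `"receptor"` and `"ligand"` for a
#' complex). Atoms live in a tibble so the usual dplyr verbs apply; 3-D
#' coordinates are carried as `x`, `y`, `z` columns in Angstrom.
#'
#' @param atoms Tibble with one row per atom. Required columns: `serial`
#'   (1..n), `name`, `element`, `residue_name`, `residue_index`, `chain_id`,
#'   `x`, `y`, `z`, `charge` (e), `lj_sigma` (A), `lj_epsilon` (kcal/mol),
#'   `mass` (amu), `gb_radius` (A, intrinsic Born radius), `is_backbone`.
#' @param bonds Two-column integer matrix of bonded atom index pairs (may have
#'   zero rows).
#' @param groups Named list of integer atom-index vectors.
#'
#' @return An object of class `bs_structure`.
#' @export
bs_structure <- function(atoms, bonds = matrix(integer(), ncol = 2), groups = list()) {
  atoms <- as_tibble(atoms)
  req <- c("serial", "name", "element", "residue_name", "residue_index",
           "chain_id", "x", "y", "z", "charge", "lj_sigma", "lj_epsilon",
           "mass", "gb_radius", "is_backbone")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("atoms table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(atoms)
  if (!identical(as.integer(atoms$serial), seq_len(n))) {
    abort("atom serials must be unique and contiguous starting at 1")
  }
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) abort("non-finite coordinates")
  if (any(atoms$mass <= 0)) abort("atom masses must be positive")
  if (any(atoms$lj_sigma < 0) || any(atoms$lj_epsilon < 0)) {
    abort("Lennard-Jones parameters must be non-negative")
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && (any(bonds < 1L) || any(bonds > n))) {
    abort("bond references an atom index outside 1..n_atoms")
  }
  groups <- lapply(groups, as.integer)
  for (g in names(groups)) {
    if (length(groups[[g]]) && (any(groups[[g]] < 1L) || any(groups[[g]] > n))) {
      abort(paste0("group '", g, "' references an invalid atom index"))
    }
  }
  if (all(c("receptor", "ligand") %in% names(groups)) &&
      length(intersect(groups$receptor, groups$ligand))) {
    abort("'receptor' and 'ligand' groups must be disjoint")
  }
  structure(list(atoms = atoms, bonds = bonds, groups = groups),
            class = "bs_structure")
}

#' @export
print.bs_structure <- function(x, ...) {
  cat("<bs_structure> ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds, groups: ",
      if (length(x$groups)) paste(names(x$groups), collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

#' Extract the coordinate matrix of a structure
#'
#' @param structure A [bs_structure()].
#' @return An `n_atoms x 3` numeric matrix (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Resolve a named group to atom indices
#'
#' @param structure A [bs_structure()].
#' @param group A group name, an integer index vector, or `NULL` for all atoms.
#' @return Integer atom indices.
#' @export
atom_group <- function(structure, group) {
  if (is.null(group)) return(seq_len(nrow(structure$atoms)))
  if (is.character(group) && length(group) == 1) {
    if (!group %in% names(structure$groups)) {
      abort(paste0("unknown atom group '", group, "'"))
    }
    return(structure$groups[[group]])
  }
  as.integer(group)
}

#' Trajectory container
#'
#' Ordered coordinate frames over the fixed atom roster of a structure.
#'
#' @param structure A [bs_structure()].
#' @param frames Numeric array `n_frames x n_atoms x 3` (Angstrom) or a list of
#'   `n_atoms x 3` matrices.
#' @param times Frame times in ps; strictly increasing. Defaults to
#'   `0, 1, 2, ...` ps.
#' @param dt0 Nominal frame spacing (ps) of the parent trajectory; used to
#'   anchor window strides on the original time grid so that window selection
#'   is idempotent. Defaults to the smallest spacing in `times`.
#' @return An object of class `bs_trajectory`.
#' @export
bs_trajectory <- function(structure, frames, times = NULL, dt0 = NULL) {
  stopifnot(inherits(structure, "bs_structure"))
  n_atoms <- nrow(structure$atoms)
  if (is.list(frames)) {
    arr <- array(NA_real_, c(length(frames), n_atoms, 3))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  if (length(dim(frames)) != 3 || dim(frames)[2] != n_atoms || dim(frames)[3] != 3) {
    abort("frames must be an n_frames x n_atoms x 3 array matching the atom roster")
  }
  nf <- dim(frames)[1]
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1)
  if (length(times) != nf || (nf > 1 && any(diff(times) <= 0))) {
    abort("frame_times must match frame count and be strictly increasing")
  }
  if (is.null(dt0)) dt0 <- if (nf > 1) min(diff(times)) else 1
  structure(list(structure = structure, coords = frames, times = times, dt0 = dt0),
            class = "bs_trajectory")
}

#' @export
print.bs_trajectory <- function(x, ...) {
  cat("<bs_trajectory> ", n_frames(x), " frames x ", dim(x$coords)[2],
      " atoms, t = [", x$times[1], ", ", x$times[n_frames(x)], "] ps\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [bs_trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as a coordinate matrix
#' @param traj A [bs_trajectory()].
#' @param i Frame index (1-based).
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) abort("frame index out of range")
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Analysis window
#'
#' A time window with an optional frame stride, used to restrict estimators to
#' e.g. the equilibrated tail of a trajectory.
#'
#' @param start_time,end_time Window bounds in ps (inclusive).
#' @param stride Keep every `stride`-th frame within the window.
#' @return An object of class `bs_window`.
#' @export
analysis_window <- function(start_time, end_time, stride = 1L) {
  if (start_time >= end_time) abort("window start must precede end")
  stride <- as.integer(stride)
  if (stride < 1L) abort("stride must be >= 1")
  structure(list(start_time = start_time, end_time = end_time, stride = stride),
            class = "bs_window")
}

#' Convenience window over the last fraction of a trajectory
#'
#' @param traj A [bs_trajectory()].
#' @param fraction Fraction of the time span to keep, from the end.
#' @param stride Frame stride.
#' @return A [analysis_window()].
#' @export
last_fraction_window <- function(traj, fraction = 0.2, stride = 1L) {
  t0 <- traj$times[1]; t1 <- traj$times[n_frames(traj)]
  analysis_window(t1 - fraction * (t1 - t0), t1 + 1e-9, stride)
}

#' Restrict a trajectory to an analysis window
#'
#' Keeps frames with `start_time <= t <= end_time`, subsampled by the window
#' stride. The stride acts on the trajectory's original time grid (every
#' `stride`-th original frame position inside the window), so applying the same
#' window twice gives the same result as applying it once.
#'
#' @param traj A [bs_trajectory()].
#' @param window A [analysis_window()].
#' @return A [bs_trajectory()] over the selected frames.
#' @export
select_window <- function(traj, window) {
  stopifnot(inherits(window, "bs_window"))
  keep <- which(traj$times >= window$start_time & traj$times <= window$end_time)
  if (!length(keep)) abort("analysis window selects no frames")
  if (window$stride > 1L) {
    phase <- (traj$times[keep] - traj$times[keep[1]]) / traj$dt0
    keep <- keep[abs(phase %% window$stride) < 1e-6 |
                 abs(phase %% window$stride - window$stride) < 1e-6]
  }
  if (!length(keep)) abort("analysis window selects no frames")
  bs_trajectory(traj$structure,
                traj$coords[keep, , , drop = FALSE],
                traj$times[keep],
                dt0 = traj$dt0)
}
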