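#' Read a per-atom topology parameter table
#'
#' The topology file is tab-separated text with one atom record per line and a
#' header. Required columns: `residue_name`, `atom_name`, `element`, `charge`
#' (e), `lj_sigma` (A), `lj_epsilon` (kcal/mol), `mass` (amu), `gb_radius` (A),
#' `is_backbone` (TRUE/FALSE). Optional: `is_donor`, `is_acceptor` flags used
#' by the hydrogen-bond detector (element-based fallback otherwise). Records
#' are keyed by `(residue_name, atom_name)`.
#'
#' @param path Path to the topology file.
#' @return A tibble of atom parameter records.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) abort(paste0("topology file not found: ", path))
  top <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  req <- c("residue_name", "atom_name", "element", "charge", "lj_sigma",
           "lj_epsilon", "mass", "gb_radius", "is_backbone")
  missing_cols <- setdiff(req, names(top))
  if (length(missing_cols)) {
    abort(paste0("topology is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(top[, c("residue_name", "atom_name")])) {
    abort("duplicate (residue_name, atom_name) topology records")
  }
  top
}

#' Write a topology parameter table
#'
#' @param topology Tibble as returned by [read_topology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  readr::write_tsv(topology, path)
  invisible(path)
}

#' Build a topology table from a parameterized structure
#'
#' One record per distinct `(residue_name, atom_name)`; useful for persisting
#' generated complexes.
#'
#' @param structure A [bs_structure()].
#' @return Topology tibble.
#' @export
topology_from_structure <- function(structure) {
  structure$atoms |>
    dplyr::distinct(.data$residue_name, .data$name, .keep_all = TRUE) |>
    dplyr::transmute(residue_name = .data$residue_name,
                     atom_name = .data$name,
                     element = .data$element,
                     charge = .data$charge,
                     lj_sigma = .data$lj_sigma,
                     lj_epsilon = .data$lj_epsilon,
                     mass = .data$mass,
                     gb_radius = .data$gb_radius,
                     is_backbone = .data$is_backbone)
}

# Assign receptor/ligand groups: protein chains vs ligand residues.
# Ligand atoms are those whose residue name matches `ligand_resname`.
.derive_groups <- function(atoms, ligand_resname = "LIG") {
  lig <- which(atoms$residue_name == ligand_resname)
  rec <- setdiff(seq_len(nrow(atoms)), lig)
  list(receptor = rec, ligand = lig)
}

#' Read a parameterized structure from PDB + topology
#'
#' Parses a (single-model) PDB file with \pkg{bio3d} and attaches per-atom
#' charges, Lennard-Jones parameters, masses and intrinsic Born radii from a
#' topology table keyed by `(residue_name, atom_name)`. Atoms whose residue
#' name equals `ligand_resname` form the `"ligand"` group; all others the
#' `"receptor"` group.
#'
#' @param path PDB file path.
#' @param topology_path Topology file path (see [read_topology()]).
#' @param ligand_resname Residue name identifying ligand atoms.
#' @param allow_missing If `TRUE`, atoms without a topology record get zero
#'   charge/LJ, carbon-like mass and radius, and a warning instead of an error.
#' @return A [bs_structure()].
#' @export
read_structure <- function(path, topology_path, ligand_resname = "LIG",
                           allow_missing = FALSE) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  top <- read_topology(topology_path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  atoms <- tibble(
    serial = seq_len(nrow(at)),
    name = trimws(at$elety),
    element = trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                            substr(trimws(at$elety), 1, 1), at$elesy)),
    residue_name = trimws(at$resid),
    residue_index = as.integer(at$resno),
    chain_id = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z
  )
  key <- paste(atoms$residue_name, atoms$name)
  tkey <- paste(top$residue_name, top$atom_name)
  idx <- match(key, tkey)
  if (anyNA(idx)) {
    miss <- unique(key[is.na(idx)])
    msg <- paste0("atoms without topology entry: ", paste(miss, collapse = "; "))
    if (!allow_missing) abort(msg)
    warn(msg)
  }
  pull_par <- function(col, default) {
    out <- top[[col]][idx]
    out[is.na(idx)] <- default
    out
  }
  atoms$charge <- pull_par("charge", 0)
  atoms$lj_sigma <- pull_par("lj_sigma", 0)
  atoms$lj_epsilon <- pull_par("lj_epsilon", 0)
  atoms$mass <- pull_par("mass", 12.011)
  atoms$gb_radius <- pull_par("gb_radius", 1.7)
  atoms$is_backbone <- as.logical(pull_par("is_backbone", FALSE))
  if ("is_donor" %in% names(top)) atoms$is_donor <- as.logical(pull_par("is_donor", NA))
  if ("is_acceptor" %in% names(top)) atoms$is_acceptor <- as.logical(pull_par("is_acceptor", NA))

  bonds <- .infer_bonds(atoms)
  bs_structure(atoms, bonds, .derive_groups(atoms, ligand_resname))
}

# Distance-based bond inference: covalent if r < 0.6 * (sigma_i + sigma_j) or,
# for X-H pairs, r < 1.25 A. Adequate for the desk-scale systems handled here.
.infer_bonds <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(), ncol = 2))
  d <- as.matrix(stats::dist(xyz))
  is_h <- atoms$element == "H"
  cut <- matrix(1.8, n, n)
  cut[is_h, ] <- 1.25; cut[, is_h] <- 1.25
  cut[is_h, is_h] <- 0   # no H-H bonds
  hit <- which(d > 0 & d < cut & upper.tri(d), arr.ind = TRUE)
  # never bond across the receptor/ligand boundary
  same_res_chain <- abs(atoms$residue_index[hit[, 1]] - atoms$residue_index[hit[, 2]]) <= 1 &
    atoms$chain_id[hit[, 1]] == atoms$chain_id[hit[, 2]]
  hit <- hit[same_res_chain, , drop = FALSE]
  matrix(as.integer(hit), ncol = 2)
}

#' Write a structure (or trajectory) as PDB
#'
#' Multi-frame input produces a multi-model PDB delimited by MODEL/ENDMDL.
#'
#' @param x A [bs_structure()] or [bs_trajectory()].
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_pdb_file <- function(x, path) {
  if (inherits(x, "bs_trajectory")) {
    st <- x$structure
    xyz <- t(apply(x$coords, 1, function(m) as.vector(t(m))))
  } else {
    st <- x
    xyz <- matrix(as.vector(t(coords(st))), nrow = 1)
  }
  at <- st$atoms
  bio3d::write.pdb(file = path,
                   xyz = xyz,
                   type = rep("ATOM", nrow(at)),
                   eleno = at$serial,
                   elety = at$name,
                   resid = at$residue_name,
                   chain = at$chain_id,
                   resno = at$residue_index,
                   elesy = at$element)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' Each MODEL block must match the atom roster of `structure`; a mismatch is
#' reported with the offending model number. Frame times default to uniform
#' `dt` spacing starting at `t0` when the file carries none (PDB never does).
#'
#' @param path Multi-model PDB path.
#' @param structure The parameterized [bs_structure()] the frames refer to.
#' @param dt Frame spacing, ps.
#' @param t0 Time of the first frame, ps.
#' @return A [bs_trajectory()].
#' @export
read_trajectory <- function(path, structure, dt = 1, t0 = 0) {
  if (!file.exists(path)) abort(paste0("trajectory file not found: ", path))
  n_atoms <- nrow(structure$atoms)
  # pre-scan MODEL blocks so atom-count mismatches name the model
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (length(starts)) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts)) abort("unbalanced MODEL/ENDMDL records")
    for (m in seq_along(starts)) {
      cnt <- sum(grepl("^(ATOM  |HETATM)", lines[starts[m]:ends[m]]))
      if (cnt != n_atoms) {
        abort(paste0("model ", m, " has ", cnt, " atoms; expected ", n_atoms))
      }
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  if (ncol(xyz) != 3 * n_atoms) {
    abort(paste0("trajectory atom count ", ncol(xyz) / 3,
                 " does not match structure (", n_atoms, ")"))
  }
  arr <- array(NA_real_, c(nf, n_atoms, 3))
  for (i in seq_len(nf)) arr[i, , ] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  bs_trajectory(structure, arr, times = t0 + dt * (seq_len(nf) - 1))
}

#' Write a uniform record table as TSV
#'
#' Energies (any numeric column) are written with 2 decimals; rows are stably
#' sorted by the declared key columns so output is deterministic.
#'
#' @param records Data frame / tibble of uniform records (may have zero rows).
#' @param path Output path.
#' @param sort_by Character vector of key columns for the stable row order
#'   (default: none, keep input order).
#' @param digits Decimal places for numeric columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, sort_by = NULL, digits = 2) {
  records <- as_tibble(records)
  if (!is.null(sort_by) && nrow(records)) {
    records <- dplyr::arrange(records, dplyr::across(dplyr::all_of(sort_by)))
  }
  out <- records |>
    mutate(across(dplyr::where(is.double), ~ formatC(.x, format = "f", digits = digits)))
  readr::write_tsv(out, path)
  invisible(path)
}
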