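#' Assemble an energy breakdown row
#'
#' Builds the standard MM/GBSA term table from its four components, with
#' `E_gas = E_vdW + E_ele` and `E_solv = E_GB + E_surf` maintained by
#' construction.
#'
#' @param E_vdW,E_ele,E_GB,E_surf Component energies, kcal/mol (vectorized).
#' @param context `"complex"`, `"receptor"`, `"ligand"` or `"delta"`.
#' @return One-row (per input element) tibble with the four components plus
#'   `E_gas` and `E_solv`.
#' @export
energy_breakdown <- function(E_vdW, E_ele, E_GB, E_surf, context = "delta") {
  tibble(context = context, E_vdW = E_vdW, E_ele = E_ele, E_GB = E_GB,
         E_surf = E_surf, E_gas = E_vdW + E_ele, E_solv = E_GB + E_surf)
}

#' Accounting identities of an energy breakdown
#'
#' Partitions a breakdown into polar (`E_ele + E_GB`) and nonpolar
#' (`E_vdW + E_surf`) contributions and reports the van der Waals minus
#' electrostatic difference.
#'
#' @param breakdown A row from [energy_breakdown()].
#' @return Tibble with `polar`, `nonpolar`, `vdw_minus_ele` (kcal/mol).
#' @export
energy_accounting <- function(breakdown) {
  tibble(polar = breakdown$E_ele + breakdown$E_GB,
         nonpolar = breakdown$E_vdW + breakdown$E_surf,
         vdw_minus_ele = breakdown$E_vdW - breakdown$E_ele)
}

#' Assemble a binding free energy from its delta breakdown and entropy
#'
#' `enthalpy = E_gas + E_solv` and `delta_G = enthalpy - T_delta_S`, exact by
#' construction.
#'
#' @param delta Delta-context row from [energy_breakdown()].
#' @param T_delta_S Entropy term T*dS, kcal/mol.
#' @param sd Optional tibble of per-term standard deviations.
#' @param n_frames_energy,n_frames_entropy Frame counts used.
#' @return A `bs_binding_energy` object.
#' @export
binding_free_energy <- function(delta, T_delta_S, sd = NULL,
                                n_frames_energy = NA_integer_,
                                n_frames_entropy = NA_integer_) {
  enthalpy <- delta$E_gas + delta$E_solv
  structure(list(delta = delta, enthalpy = enthalpy, T_delta_S = T_delta_S,
                 delta_G = enthalpy - T_delta_S, sd = sd,
                 n_frames_energy = n_frames_energy,
                 n_frames_entropy = n_frames_entropy),
            class = "bs_binding_energy")
}

#' @export
print.bs_binding_energy <- function(x, ...) {
  cat("<bs_binding_energy>\n")
  print(tidy(x))
  cat(sprintf("delta_G = %.2f kcal/mol (enthalpy %.2f - T*dS %.2f)\n",
              x$delta_G, x$enthalpy, x$T_delta_S))
  invisible(x)
}

#' @rdname binding_free_energy
#' @param x A `bs_binding_energy`.
#' @param ... Unused.
#' @export
tidy.bs_binding_energy <- function(x, ...) {
  terms <- c("E_vdW", "E_ele", "E_GB", "E_surf", "E_gas", "E_solv")
  out <- tibble(term = c(terms, "enthalpy", "T_delta_S", "delta_G"),
                estimate = c(unlist(x$delta[terms]), x$enthalpy, x$T_delta_S,
                             x$delta_G))
  if (!is.null(x$sd)) {
    out <- left_join(out, x$sd, by = "term")
  }
  out
}

#' @rdname binding_free_energy
#' @export
glance.bs_binding_energy <- function(x, ...) {
  tibble(delta_G = x$delta_G, enthalpy = x$enthalpy, T_delta_S = x$T_delta_S,
         n_frames_energy = x$n_frames_energy,
         n_frames_entropy = x$n_frames_entropy)
}

#' Single-frame binding energy delta (single-trajectory protocol)
#'
#' Receptor and ligand coordinates are taken from the same complex frame, so
#' intramolecular bonded terms cancel exactly in the delta and are never
#' computed: delta `E_vdW`/`E_ele` are the intermolecular pair sums; delta
#' `E_GB` is `E_GB(complex) - E_GB(receptor) - E_GB(ligand)` with effective
#' radii recomputed per context; delta `E_surf` analogously from
#' `gamma * SASA + beta`.
#'
#' @param structure A complex [bs_structure()] with receptor/ligand groups.
#' @param coords Frame coordinates (default: the structure's own).
#' @param params A [gb_params()].
#' @return One-row delta [energy_breakdown()] tibble.
#' @export
frame_binding_energy <- function(structure, coords = NULL, params = gb_params()) {
  xyz <- coords %||% coords(structure)
  mm <- pairwise_mm_terms(structure, xyz, "receptor", "ligand", params)
  e_gb <- gb_energy(structure, xyz, NULL, params) -
    gb_energy(structure, xyz, "receptor", params) -
    gb_energy(structure, xyz, "ligand", params)
  surf <- function(group) {
    params$surface_tension *
      sasa(structure, xyz, group, params$probe_radius, params$sasa_points)$total +
      params$surface_offset
  }
  e_surf <- surf(NULL) - surf("receptor") - surf("ligand")
  energy_breakdown(unname(mm["E_vdW"]), unname(mm["E_ele"]), e_gb, e_surf)
}

#' Frame-averaged MM/GBSA binding free energy
#'
#' Averages the per-frame delta terms over an analysis window and assembles
#' `delta_G = enthalpy - T_delta_S`. The entropy term is taken from the
#' `entropy` argument when supplied (e.g. an externally computed value);
#' otherwise it is estimated with [quasi_harmonic_entropy()] as
#' `T dS = TS(complex) - TS(receptor) - TS(ligand)` on an evenly spaced
#' subsample of at most `entropy_frames` frames.
#'
#' @param traj A complex [bs_trajectory()].
#' @param window Optional [analysis_window()].
#' @param params A [gb_params()].
#' @param entropy Optional externally supplied `T_delta_S`, kcal/mol.
#' @param entropy_frames Subsample size for the quasi-harmonic estimate.
#' @return A `bs_binding_energy` object.
#' @export
average_binding_energy <- function(traj, window = NULL, params = gb_params(),
                                   entropy = NULL, entropy_frames = 100L) {
  if (!is.null(window)) traj <- select_window(traj, window)
  nf <- n_frames(traj)
  if (nf < 2) abort("need at least 2 frames in the analysis window")
  per_frame <- purrr::map_dfr(seq_len(nf), function(f) {
    frame_binding_energy(traj$structure, frame_coords(traj, f), params)
  })
  terms <- c("E_vdW", "E_ele", "E_GB", "E_surf", "E_gas", "E_solv")
  delta <- energy_breakdown(mean(per_frame$E_vdW), mean(per_frame$E_ele),
                            mean(per_frame$E_GB), mean(per_frame$E_surf))
  sds <- tibble(term = terms,
                sd = vapply(terms, function(tm) sd(per_frame[[tm]]), 0))
  n_ent <- NA_integer_
  if (is.null(entropy)) {
    sub <- unique(round(seq(1, nf, length.out = min(entropy_frames, nf))))
    straj <- bs_trajectory(traj$structure,
                           traj$coords[sub, , , drop = FALSE],
                           traj$times[sub], dt0 = traj$dt0)
    ts <- function(group) {
      quasi_harmonic_entropy(straj, group, params$temperature)
    }
    entropy <- ts(NULL) - ts("receptor") - ts("ligand")
    n_ent <- length(sub)
  }
  binding_free_energy(delta, entropy, sd = sds,
                      n_frames_energy = nf, n_frames_entropy = n_ent)
}

#' Quasi-harmonic configurational entropy
#'
#' Mass-weighted covariance of the (optionally mean-fitted) coordinates is
#' diagonalized; each eigenvalue `lambda` defines a harmonic mode of frequency
#' `omega = sqrt(kB T / lambda)` whose quantum harmonic oscillator entropy is
#' summed. By default the frames are superposed onto their mean structure and
#' the six smallest modes are discarded as residual rigid-body motion; set
#' `fit = FALSE, drop_modes = 0` for fixtures with no overall motion.
#'
#' @param traj A [bs_trajectory()].
#' @param atom_subset Atom indices or group name (default: all atoms).
#' @param temperature K.
#' @param fit Superpose frames onto their mean structure first.
#' @param drop_modes Number of smallest modes to discard.
#' @return `T * S` in kcal/mol.
#' @export
quasi_harmonic_entropy <- function(traj, atom_subset = NULL, temperature = 300,
                                   fit = TRUE, drop_modes = 6L) {
  sub <- atom_group(traj$structure, atom_subset)
  nf <- n_frames(traj)
  if (nf <= 3 * length(sub)) {
    warn(paste0("quasi-harmonic entropy: only ", nf, " frames for ",
                3 * length(sub), " degrees of freedom; estimate may be poor"))
  }
  arr <- if (fit) .fit_to_mean(traj, sub) else traj$coords
  # frames x 3n matrix of the subset's coordinates
  X <- matrix(NA_real_, nf, 3 * length(sub))
  for (k in seq_along(sub)) {
    X[, (3 * k - 2):(3 * k)] <- arr[, sub[k], ]
  }
  m <- rep(traj$structure$atoms$mass[sub], each = 3)
  X <- sweep(X, 2, colMeans(X))
  X <- sweep(X, 2, sqrt(m), "*")
  C <- crossprod(X) / (nf - 1)           # amu A^2
  lambda <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
  keep <- lambda[lambda > 1e-10]
  if (length(keep) < length(lambda)) {
    warn("singular covariance: null modes discarded")
  }
  if (drop_modes > 0) keep <- head(keep, max(length(keep) - drop_modes, 0))
  if (!length(keep)) return(0)
  kT_J <- .const$kB_J * temperature
  omega <- sqrt(kT_J / (keep * .const$amuA2))  # 1/s
  x <- .const$hbar * omega / kT_J
  s_mode <- .const$kB * (x / (expm1(x)) - log1p(-exp(-x)))  # kcal/(mol K)
  temperature * sum(s_mode)
}

#' Per-residue decomposition of the binding enthalpy
#'
#' Splits every delta term over residues, frame by frame, then averages:
#' intermolecular vdW/electrostatic pair energies are split half to each
#' partner's residue (the ligand's halves collect under the ligand
#' pseudo-residue); generalized-Born ordered-pair energies of the complex,
#' minus the matching receptor-only/ligand-only pair energies, are assigned to
#' the first atom's residue (a symmetric half-split); per-atom surface-area
#' differences times gamma go to the atom's residue. Backbone and side-chain
#' subtotals follow each receptor atom's `is_backbone` flag; ligand atoms
#' count as side chain. Residue subtotals therefore sum exactly to the delta
#' enthalpy.
#'
#' @param traj A complex [bs_trajectory()].
#' @param window Optional [analysis_window()].
#' @param params A [gb_params()].
#' @param key_threshold Absolute subtotal (kcal/mol) at and above which a
#'   residue is flagged as key (default 0.50).
#' @return Tibble with one row per residue (receptor residues sorted by index,
#'   then the ligand pseudo-residue): `chain_id`, `residue_index`,
#'   `residue_name`, `d_vdW`, `d_ele`, `d_GB`, `d_surf`, `d_subtotal`,
#'   `sidechain_subtotal`, `backbone_subtotal`, `is_key`.
#' @export
decompose_per_residue <- function(traj, window = NULL, params = gb_params(),
                                  key_threshold = 0.5) {
  if (!is.null(window)) traj <- select_window(traj, window)
  st <- traj$structure
  at <- st$atoms
  rec <- st$groups$receptor; lig <- st$groups$ligand
  n <- nrow(at)
  # residue id per atom: receptor residues + one ligand pseudo-residue
  res_key <- paste(at$chain_id, at$residue_index, at$residue_name)
  res_key[lig] <- "LIG"
  res_levels <- c(unique(res_key[rec][order(at$chain_id[rec], at$residue_index[rec])]),
                  "LIG")
  rid <- match(res_key, res_levels)
  nres <- length(res_levels)
  part <- ifelse(at$is_backbone, "backbone", "sidechain")
  part[lig] <- "sidechain"
  nf <- n_frames(traj)

  acc <- matrix(0, nres, 4, dimnames = list(NULL, c("d_vdW", "d_ele", "d_GB", "d_surf")))
  acc_part <- matrix(0, nres, 2, dimnames = list(NULL, c("sidechain", "backbone")))

  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    # intermolecular vdW / electrostatics, pairwise matrices rec x lig
    dx <- outer(xyz[rec, 1], xyz[lig, 1], "-")
    dy <- outer(xyz[rec, 2], xyz[lig, 2], "-")
    dz <- outer(xyz[rec, 3], xyz[lig, 3], "-")
    r <- sqrt(dx^2 + dy^2 + dz^2)
    if (any(r < 0.5)) abort("atomic clash: intermolecular distance < 0.5 A")
    sig <- outer(at$lj_sigma[rec], at$lj_sigma[lig], "+") / 2
    eps <- sqrt(outer(at$lj_epsilon[rec], at$lj_epsilon[lig]))
    sr6 <- (sig / r)^6
    Evdw <- 4 * eps * (sr6^2 - sr6)
    Eele <- .const$coulomb / params$interior_dielectric *
      outer(at$charge[rec], at$charge[lig]) / r
    # GB: complex ordered-pair matrix minus same-context blocks
    Egb <- .gb_pair_matrix(st, xyz, NULL, params)
    Egb[rec, rec] <- Egb[rec, rec] - .gb_pair_matrix(st, xyz, rec, params)
    Egb[lig, lig] <- Egb[lig, lig] - .gb_pair_matrix(st, xyz, lig, params)
    # per-atom SASA differences
    a_cx <- sasa(st, xyz, NULL, params$probe_radius, params$sasa_points)$per_atom$area
    a_rec <- sasa(st, xyz, rec, params$probe_radius, params$sasa_points)$per_atom$area
    a_lig <- sasa(st, xyz, lig, params$probe_radius, params$sasa_points)$per_atom$area
    d_area <- a_cx
    d_area[rec] <- d_area[rec] - a_rec
    d_area[lig] <- d_area[lig] - a_lig
    e_atom_surf <- params$surface_tension * d_area

    # fold pair matrices into per-atom energies (half-splits)
    e_atom_vdw <- numeric(n); e_atom_ele <- numeric(n)
    e_atom_vdw[rec] <- rowSums(Evdw) / 2
    e_atom_vdw[lig] <- colSums(Evdw) / 2
    e_atom_ele[rec] <- rowSums(Eele) / 2
    e_atom_ele[lig] <- colSums(Eele) / 2
    e_atom_gb <- rowSums(Egb)

    # rowsum labels groups by value; map back into residue-level order
    sum_by_res <- function(v) {
      out <- numeric(nres)
      tmp <- rowsum(v, rid)
      out[as.integer(rownames(tmp))] <- tmp
      out
    }
    acc[, "d_vdW"] <- acc[, "d_vdW"] + sum_by_res(e_atom_vdw)
    acc[, "d_ele"] <- acc[, "d_ele"] + sum_by_res(e_atom_ele)
    acc[, "d_GB"] <- acc[, "d_GB"] + sum_by_res(e_atom_gb)
    acc[, "d_surf"] <- acc[, "d_surf"] + sum_by_res(e_atom_surf)
    e_atom_total <- e_atom_vdw + e_atom_ele + e_atom_gb + e_atom_surf
    for (p in c("sidechain", "backbone")) {
      sel <- part == p
      v <- numeric(n); v[sel] <- e_atom_total[sel]
      acc_part[, p] <- acc_part[, p] + sum_by_res(v)
    }
  }
  acc <- acc / nf; acc_part <- acc_part / nf

  parts <- strsplit(res_levels, " ", fixed = TRUE)
  chain <- vapply(parts, function(p) if (length(p) == 3) p[1] else NA_character_, "")
  ridx <- vapply(parts, function(p) if (length(p) == 3) as.integer(p[2]) else NA_integer_, 0L)
  rname <- vapply(parts, function(p) if (length(p) == 3) p[3] else "LIG", "")
  tibble(chain_id = chain,
         residue_index = ridx,
         residue_name = rname,
         d_vdW = acc[, "d_vdW"], d_ele = acc[, "d_ele"],
         d_GB = acc[, "d_GB"], d_surf = acc[, "d_surf"],
         d_subtotal = rowSums(acc),
         sidechain_subtotal = acc_part[, "sidechain"],
         backbone_subtotal = acc_part[, "backbone"],
         is_key = abs(rowSums(acc)) >= key_threshold)
}

#' Sum the four printed components of a decomposition row
#'
#' The subtotal identity of a per-residue contribution:
#' `d_subtotal = d_vdW + d_ele + d_GB + d_surf`.
#'
#' @param d_vdW,d_ele,d_GB,d_surf Component contributions, kcal/mol
#'   (vectorized).
#' @return Numeric subtotal(s).
#' @export
residue_subtotal <- function(d_vdW, d_ele, d_GB, d_surf) {
  d_vdW + d_ele + d_GB + d_surf
}
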