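#' Planted hydrogen bond specification
#'
#' Describes a donor-H...acceptor triple whose geometry the trajectory
#' generator controls frame by frame: with probability `target_occupancy` the
#' frame is "bound" (donor-acceptor distance near `bound_distance`, acceptor-H
#' -donor angle drawn uniform in 150-180 deg), otherwise "unbound" (distance
#' near `unbound_distance`, angle uniform in 60-110 deg).
#'
#' @param donor_index,hydrogen_index,acceptor_index Atom indices in the
#'   generated complex.
#' @param target_occupancy Fraction of bound frames, in `[0, 1]`.
#' @param bound_distance Bound donor-acceptor distance, A (`< 3.5`).
#' @param unbound_distance Unbound distance, A (`> 3.5`).
#' @param noise_sd Gaussian distance noise, A. Must leave 3 sd of clearance on
#'   both sides of the 3.5 A detection threshold.
#' @return A `bs_planted_hbond` list.
#' @export
planted_hbond <- function(donor_index, hydrogen_index, acceptor_index,
                          target_occupancy, bound_distance = 2.9,
                          unbound_distance = 5.5, noise_sd = 0.1) {
  if (target_occupancy < 0 || target_occupancy > 1) {
    abort("target_occupancy must be in [0, 1]")
  }
  if (!(bound_distance + 3 * noise_sd < 3.5 && 3.5 < unbound_distance - 3 * noise_sd)) {
    abort("bound/unbound distances must clear 3.5 A by at least 3 noise sd")
  }
  structure(list(donor_index = as.integer(donor_index),
                 hydrogen_index = as.integer(hydrogen_index),
                 acceptor_index = as.integer(acceptor_index),
                 target_occupancy = target_occupancy,
                 bound_distance = bound_distance,
                 unbound_distance = unbound_distance,
                 noise_sd = noise_sd),
            class = "bs_planted_hbond")
}

#' Synthetic complex specification
#'
#' Seeded recipe for a toy receptor-ligand complex and its trajectory, with
#' known ground truth: planted hydrogen-bond occupancies, planted heavy-atom
#' contact distances (Gaussian), and isotropic harmonic-like positional jitter
#' everywhere else. Frames are drawn i.i.d.; the generator emulates the
#' frame-average statistics of an equilibrated trajectory, not its dynamics.
#'
#' @param n_receptor_residues Number of poly-alanine-like receptor residues.
#' @param n_ligand_atoms Number of rigid ligand atoms.
#' @param n_frames Trajectory length in frames.
#' @param planted_hbonds List of [planted_hbond()] objects (indices refer to
#'   the complex generated from this spec).
#' @param planted_contacts List of `list(pair = c(i, j), mean = A, sd = A)`;
#'   atom `j` is repositioned along the reference `i -> j` direction each frame
#'   so the pair distance is `N(mean, sd)`.
#' @param fluctuation_sd_per_atom Isotropic jitter sd per coordinate, A.
#' @param ligand_charges Optional per-atom ligand charges (e); defaults to
#'   small alternating partial charges. A single ligand atom with charge +1
#'   makes a Born-ion test case.
#' @param dt Frame spacing, ps.
#' @param seed Integer seed fixing all randomness.
#' @return A `bs_synthetic_spec` list.
#' @export
synthetic_spec <- function(n_receptor_residues = 10,
                           n_ligand_atoms = 8,
                           n_frames = 200,
                           planted_hbonds = list(),
                           planted_contacts = list(),
                           fluctuation_sd_per_atom = 0.25,
                           ligand_charges = NULL,
                           dt = 1,
                           seed = 1L) {
  if (n_receptor_residues < 1 || n_ligand_atoms < 1 || n_frames < 1) {
    abort("counts must be positive")
  }
  structure(list(n_receptor_residues = as.integer(n_receptor_residues),
                 n_ligand_atoms = as.integer(n_ligand_atoms),
                 n_frames = as.integer(n_frames),
                 planted_hbonds = planted_hbonds,
                 planted_contacts = planted_contacts,
                 fluctuation_sd_per_atom = fluctuation_sd_per_atom,
                 ligand_charges = ligand_charges,
                 dt = dt,
                 seed = as.integer(seed)),
            class = "bs_synthetic_spec")
}

# Per-element parameter presets (Amber-like LJ, Bondi-like Born radii).
.elem_params <- function(element) {
  tab <- list(
    H = list(sigma = 1.069, eps = 0.0157, mass = 1.008,  rad = 1.20),
    C = list(sigma = 3.400, eps = 0.0860, mass = 12.011, rad = 1.70),
    N = list(sigma = 3.250, eps = 0.1700, mass = 14.007, rad = 1.55),
    O = list(sigma = 2.960, eps = 0.2100, mass = 15.999, rad = 1.50),
    S = list(sigma = 3.564, eps = 0.2500, mass = 32.06,  rad = 1.80),
    F = list(sigma = 3.118, eps = 0.0610, mass = 18.998, rad = 1.47)
  )
  out <- tab[[element]]
  if (is.null(out)) tab[["C"]] else out
}

#' Generate a toy receptor-ligand complex
#'
#' Builds a self-avoiding poly-alanine-like receptor chain (atoms N, H, CA, C,
#' O, CB per residue, neutral per-residue charge pattern) along the x axis and
#' places a rigid multi-atom ligand in a shallow pocket above the chain
#' mid-point. All atoms carry charges, Lennard-Jones parameters, masses and
#' intrinsic Born radii, so every downstream energy stage runs on the output.
#' Deterministic: the same spec always yields byte-identical structures.
#'
#' @param spec A [synthetic_spec()].
#' @return A [bs_structure()] with `"receptor"` and `"ligand"` groups.
#' @export
generate_complex <- function(spec) {
  stopifnot(inherits(spec, "bs_synthetic_spec"))
  nres <- spec$n_receptor_residues
  # offsets (A) of the 6 residue atoms relative to the CA position
  offs <- rbind(N  = c(-1.10, 0.90, 0.00),
                H  = c(-1.10, 1.92, 0.00),
                CA = c( 0.00, 0.00, 0.00),
                C  = c( 1.20, 0.85, 0.00),
                O  = c( 1.30, 0.85, 1.15),
                CB = c( 0.00, -1.05, -1.05))
  elems  <- c("N", "H", "C", "C", "O", "C")
  charges <- c(-0.42, 0.27, 0.03, 0.60, -0.50, 0.02)
  bb <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)

  rows <- vector("list", nres)
  for (i in seq_len(nres)) {
    ca <- c(3.8 * (i - 1), 0, 0)
    pos <- sweep(offs, 2, ca, "+")
    rows[[i]] <- tibble(
      name = rownames(offs), element = elems,
      residue_name = "ALA", residue_index = i, chain_id = "A",
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      charge = charges, is_backbone = bb)
  }
  atoms <- bind_rows(rows)

  # rigid ligand: zig-zag chain hovering over the chain mid-point
  nl <- spec$n_ligand_atoms
  mid <- 3.8 * (floor(nres / 2))
  k <- seq_len(nl) - 1
  lig_elem <- rep("C", nl)
  if (nl >= 1) lig_elem[1] <- "N"
  if (nl >= 4) lig_elem[4] <- "O"
  if (nl >= 7) lig_elem[7] <- "N"
  lig_charge <- spec$ligand_charges
  if (is.null(lig_charge)) {
    lig_charge <- rep_len(c(-0.1, 0.1), nl)
    if (nl %% 2 == 1) lig_charge[nl] <- 0  # keep the ligand neutral
  }
  if (length(lig_charge) != nl) abort("ligand_charges length must equal n_ligand_atoms")
  lig <- tibble(
    name = paste0(lig_elem, seq_len(nl)),
    element = lig_elem,
    residue_name = "LIG", residue_index = 1L, chain_id = "L",
    x = mid - 0.65 * (nl - 1) + 1.3 * k,
    y = 0.9 + 0.5 * (k %% 2),
    z = 4.2 + 0.3 * (k %% 2),
    charge = lig_charge, is_backbone = FALSE)
  atoms <- bind_rows(atoms, lig)

  par <- lapply(atoms$element, .elem_params)
  atoms <- atoms |>
    mutate(serial = row_number(),
           lj_sigma = vapply(par, `[[`, 0, "sigma"),
           lj_epsilon = vapply(par, `[[`, 0, "eps"),
           mass = vapply(par, `[[`, 0, "mass"),
           gb_radius = vapply(par, `[[`, 0, "rad")) |>
    select("serial", dplyr::everything())

  # bonds: within-residue backbone/sidechain + peptide + consecutive ligand
  per_res <- 6L
  bond <- list()
  for (i in seq_len(nres)) {
    b0 <- (i - 1L) * per_res
    bond[[length(bond) + 1L]] <- cbind(b0 + c(1L, 1L, 3L, 4L, 3L),
                                       b0 + c(2L, 3L, 4L, 5L, 6L))
    if (i < nres) bond[[length(bond) + 1L]] <- cbind(b0 + 4L, b0 + per_res + 1L)
  }
  l0 <- nres * per_res
  if (nl > 1) bond[[length(bond) + 1L]] <- cbind(l0 + k[-nl] + 1L, l0 + k[-nl] + 2L)
  bonds <- do.call(rbind, bond)

  st <- bs_structure(atoms, bonds, .derive_groups(atoms))
  dmin <- .min_interatomic_distance(coords(st))
  if (dmin <= 1.0) abort("generated geometry has interatomic distance <= 1.0 A")
  st
}

.min_interatomic_distance <- function(xyz) min(stats::dist(xyz))

# Place the acceptor so that |A - D| = d and angle(A-H-D, vertex H) = theta.
# b = |H - D| (the covalent bond), u = unit(H - D), v any unit vector normal
# to u. Solving |A - D| = d for the distance t = |A - H| gives
# t = b cos(theta) + sqrt(d^2 - b^2 sin^2(theta)).
.place_acceptor <- function(D, H, d, theta_deg, v_hint = c(0, 0, 1)) {
  u <- H - D; b <- sqrt(sum(u^2)); u <- u / b
  v <- v_hint - sum(v_hint * u) * u
  if (sum(v^2) < 1e-8) {
    v <- c(1, 0, 0) - u[1] * u
  }
  v <- v / sqrt(sum(v^2))
  th <- theta_deg * pi / 180
  disc <- d^2 - (b * sin(th))^2
  t <- b * cos(th) + sqrt(max(disc, 0))
  H + t * (cos(th) * (-u) + sin(th) * v)
}

#' Generate a synthetic trajectory with planted ground truth
#'
#' Frames are drawn independently. Per frame: receptor atoms get isotropic
#' Gaussian jitter; ligand atoms move rigidly by one shared Gaussian
#' translation; each planted contact's second atom is repositioned along the
#' reference pair direction to a `N(mean, sd)` distance; each planted hydrogen
#' bond is set to bound geometry with probability `target_occupancy` (see
#' [planted_hbond()]). Atoms controlled by a planted feature are exempt from
#' generic jitter (for ligand-borne acceptors this locally overrides ligand
#' rigidity).
#'
#' @param structure Complex from [generate_complex()].
#' @param spec The same [synthetic_spec()].
#' @return A [bs_trajectory()] with `spec$n_frames` frames.
#' @export
generate_trajectory <- function(structure, spec) {
  stopifnot(inherits(structure, "bs_structure"), inherits(spec, "bs_synthetic_spec"))
  ref <- coords(structure)
  n <- nrow(ref)
  nf <- spec$n_frames
  lig_idx <- structure$groups$ligand
  controlled <- integer()
  for (hb in spec$planted_hbonds) {
    controlled <- c(controlled, hb$donor_index, hb$hydrogen_index, hb$acceptor_index)
  }
  for (pc in spec$planted_contacts) controlled <- c(controlled, pc$pair[2])
  controlled <- unique(controlled)
  free_rec <- setdiff(setdiff(seq_len(n), lig_idx), controlled)
  free_lig <- setdiff(lig_idx, controlled)

  withr::with_seed(spec$seed, {
    arr <- array(NA_real_, c(nf, n, 3))
    sdj <- spec$fluctuation_sd_per_atom
    for (f in seq_len(nf)) {
      xyz <- ref
      if (length(free_rec)) {
        xyz[free_rec, ] <- xyz[free_rec, ] +
          matrix(rnorm(3 * length(free_rec), 0, sdj), ncol = 3)
      }
      if (length(free_lig)) {
        xyz[free_lig, ] <- sweep(xyz[free_lig, , drop = FALSE], 2,
                                 rnorm(3, 0, sdj), "+")
      }
      for (pc in spec$planted_contacts) {
        i <- pc$pair[1]; j <- pc$pair[2]
        dir <- ref[j, ] - ref[i, ]
        dir <- dir / sqrt(sum(dir^2))
        xyz[j, ] <- xyz[i, ] + dir * rnorm(1, pc$mean, pc$sd)
      }
      for (hb in spec$planted_hbonds) {
        D <- ref[hb$donor_index, ]; H <- ref[hb$hydrogen_index, ]
        xyz[hb$donor_index, ] <- D
        xyz[hb$hydrogen_index, ] <- H
        bound <- runif(1) < hb$target_occupancy
        d <- rnorm(1, if (bound) hb$bound_distance else hb$unbound_distance, hb$noise_sd)
        th <- if (bound) runif(1, 150, 180) else runif(1, 60, 110)
        xyz[hb$acceptor_index, ] <- .place_acceptor(D, H, d, th)
      }
      arr[f, , ] <- xyz
    }
    bs_trajectory(structure, arr, times = spec$dt * (seq_len(nf) - 1))
  })
}

#' Generate an exactly Boltzmann-sampled harmonic trajectory
#'
#' Independent 3-D harmonic wells: every Cartesian coordinate of every atom is
#' drawn `N(ref, sqrt(kB T / spring_k))`, the exact classical Boltzmann
#' distribution of a harmonic oscillator. Used to validate the quasi-harmonic
#' entropy estimator against its closed form.
#'
#' @param n_atoms Number of atoms (carbon-like, mass 12.011 amu, placed on a
#'   10 A grid so wells never interfere).
#' @param spring_k Spring constant, kcal/(mol A^2).
#' @param temperature Temperature, K.
#' @param n_frames Number of i.i.d. frames.
#' @param seed Integer seed.
#' @return A [bs_trajectory()].
#' @export
generate_harmonic_trajectory <- function(n_atoms, spring_k, temperature = 300,
                                         n_frames = 10000, seed = 1L) {
  if (spring_k <= 0) abort("spring_k must be positive")
  g <- ceiling(n_atoms^(1 / 3))
  idx <- seq_len(n_atoms) - 1
  ref <- cbind(10 * (idx %% g), 10 * ((idx %/% g) %% g), 10 * (idx %/% (g * g)))
  atoms <- tibble(
    serial = seq_len(n_atoms), name = "C", element = "C",
    residue_name = "HAR", residue_index = seq_len(n_atoms), chain_id = "A",
    x = ref[, 1], y = ref[, 2], z = ref[, 3],
    charge = 0, lj_sigma = 3.4, lj_epsilon = 0.086, mass = 12.011,
    gb_radius = 1.7, is_backbone = FALSE)
  st <- bs_structure(atoms, groups = list(receptor = seq_len(n_atoms),
                                          ligand = integer()))
  sd0 <- sqrt(.const$kB * temperature / spring_k)
  withr::with_seed(as.integer(seed), {
    noise <- array(rnorm(n_frames * n_atoms * 3, 0, sd0), c(n_frames, n_atoms, 3))
  })
  arr <- sweep(noise, c(2, 3), ref, "+")
  bs_trajectory(st, arr)
}

#' Emit a synthetic complex bundle to disk
#'
#' Writes the complex PDB, its topology table, the multi-model trajectory PDB
#' and a ground-truth TSV (planted occupancies and contact distances) under a
#' common file prefix.
#'
#' @param spec A [synthetic_spec()].
#' @param prefix Output path prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_synthetic_bundle <- function(spec, prefix) {
  st <- generate_complex(spec)
  traj <- generate_trajectory(st, spec)
  paths <- c(structure = paste0(prefix, "_complex.pdb"),
             topology = paste0(prefix, "_topology.tsv"),
             trajectory = paste0(prefix, "_traj.pdb"),
             truth = paste0(prefix, "_truth.tsv"))
  write_pdb_file(st, paths["structure"])
  write_topology(topology_from_structure(st), paths["topology"])
  write_pdb_file(traj, paths["trajectory"])
  truth <- bind_rows(
    purrr::map_dfr(spec$planted_hbonds, function(hb) {
      tibble(kind = "hbond",
             atom_i = hb$donor_index, atom_j = hb$acceptor_index,
             value = hb$target_occupancy)
    }),
    purrr::map_dfr(spec$planted_contacts, function(pc) {
      tibble(kind = "contact", atom_i = pc$pair[1], atom_j = pc$pair[2],
             value = pc$mean)
    }))
  if (!nrow(truth)) truth <- tibble(kind = character(), atom_i = integer(),
                                    atom_j = integer(), value = double())
  write_table(truth, paths["truth"], digits = 4)
  invisible(paths)
}
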