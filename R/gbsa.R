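#' Generalized-Born / surface-area parameters
#'
#' Defaults follow the common OBC-II implicit-solvent setup: interior
#' dielectric 1, exterior 78.5, OBC scaling constants alpha 1.0, beta 0.8,
#' gamma 4.85, intrinsic-radius offset 0.09 A, surface tension 0.0072
#' kcal/(mol A^2) with zero offset, 1.4 A solvent probe, 300 K.
#'
#' @param interior_dielectric,exterior_dielectric Dielectric constants.
#' @param obc_alpha,obc_beta,obc_gamma OBC-II tanh rescaling constants.
#' @param offset Intrinsic Born radius offset, A.
#' @param surface_tension Nonpolar term slope gamma, kcal/(mol A^2).
#' @param surface_offset Nonpolar term intercept beta, kcal/mol.
#' @param probe_radius Solvent probe radius, A.
#' @param sasa_points Sphere sample count for Shrake-Rupley.
#' @param temperature K.
#' @return A `bs_gb_params` list.
#' @export
gb_params <- function(interior_dielectric = 1.0, exterior_dielectric = 78.5,
                      obc_alpha = 1.0, obc_beta = 0.8, obc_gamma = 4.85,
                      offset = 0.09, surface_tension = 0.0072,
                      surface_offset = 0.0, probe_radius = 1.4,
                      sasa_points = 960L, temperature = 300) {
  if (interior_dielectric <= 0 || exterior_dielectric <= interior_dielectric) {
    abort("need 0 < interior_dielectric < exterior_dielectric")
  }
  structure(list(interior_dielectric = interior_dielectric,
                 exterior_dielectric = exterior_dielectric,
                 obc_alpha = obc_alpha, obc_beta = obc_beta,
                 obc_gamma = obc_gamma, offset = offset,
                 surface_tension = surface_tension,
                 surface_offset = surface_offset,
                 probe_radius = probe_radius,
                 sasa_points = as.integer(sasa_points),
                 temperature = temperature),
            class = "bs_gb_params")
}

#' Intermolecular molecular-mechanics pair terms
#'
#' Lennard-Jones 12-6 with Lorentz-Berthelot combination and Coulomb
#' electrostatics (constant 332.0637 kcal A / (mol e^2), interior dielectric),
#' summed over all pairs between two disjoint groups. No distance cutoff.
#'
#' @param structure A [bs_structure()].
#' @param coords `n x 3` frame coordinates (default: the structure's own).
#' @param group_a,group_b Disjoint atom index sets or group names.
#' @param params A [gb_params()] (only the interior dielectric is used).
#' @return Named numeric `c(E_vdW =, E_ele =)` in kcal/mol.
#' @export
pairwise_mm_terms <- function(structure, coords = NULL, group_a = "receptor",
                              group_b = "ligand", params = gb_params()) {
  xyz <- coords %||% coords(structure)
  ia <- atom_group(structure, group_a); ib <- atom_group(structure, group_b)
  if (length(intersect(ia, ib))) abort("groups must be disjoint")
  if (!length(ia) || !length(ib)) return(c(E_vdW = 0, E_ele = 0))
  at <- structure$atoms
  dx <- outer(xyz[ia, 1], xyz[ib, 1], "-")
  dy <- outer(xyz[ia, 2], xyz[ib, 2], "-")
  dz <- outer(xyz[ia, 3], xyz[ib, 3], "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(r < 0.5)) abort("atomic clash: intermolecular distance < 0.5 A")
  sig <- outer(at$lj_sigma[ia], at$lj_sigma[ib], "+") / 2
  eps <- sqrt(outer(at$lj_epsilon[ia], at$lj_epsilon[ib]))
  sr6 <- (sig / r)^6
  e_vdw <- sum(4 * eps * (sr6^2 - sr6))
  e_ele <- .const$coulomb / params$interior_dielectric *
    sum(outer(at$charge[ia], at$charge[ib]) / r)
  c(E_vdW = e_vdw, E_ele = e_ele)
}

# Element-based HCT descreening scale factors.
.gb_screen <- function(element) {
  s <- c(H = 0.85, C = 0.72, N = 0.79, O = 0.85, S = 0.96, F = 0.88, P = 0.86)
  out <- unname(s[element])
  out[is.na(out)] <- 0.8
  out
}

#' Effective Born radii (OBC-II)
#'
#' Pairwise HCT descreening integrals rescaled through the OBC tanh form:
#' `1/R_eff = 1/rho_i - tanh(a*Psi - b*Psi^2 + c*Psi^3) / R_i` with
#' `rho_i = R_i - offset` and `Psi = rho_i * I_i`. An isolated atom's
#' effective radius is exactly `rho_i`; burial can only grow the radius.
#'
#' @param structure A [bs_structure()].
#' @param coords Frame coordinates (default: the structure's own).
#' @param params A [gb_params()].
#' @param group Atom subset defining the solute (default: all atoms). Radii
#'   are computed for these atoms in isolation from the rest.
#' @return Numeric vector of effective radii (A) for the group's atoms.
#' @export
born_radii <- function(structure, coords = NULL, params = gb_params(),
                       group = NULL) {
  xyz <- coords %||% coords(structure)
  idx <- atom_group(structure, group)
  at <- structure$atoms
  R <- at$gb_radius[idx]
  if (any(R <= 0)) abort("nonpositive intrinsic Born radius")
  rho <- R - params$offset
  if (any(rho <= 0)) abort("intrinsic radius smaller than the GB offset")
  n <- length(idx)
  if (n == 1) return(1 / (1 / rho))
  P <- xyz[idx, , drop = FALSE]
  s <- .gb_screen(at$element[idx])
  dm <- as.matrix(stats::dist(P))
  I <- numeric(n)
  for (i in seq_len(n)) {
    r <- dm[i, -i]
    sr <- (s * rho)[-i]
    U <- r + sr
    L <- pmax(rho[i], abs(r - sr))
    keep <- rho[i] < U  # pair contributes only if j's scaled sphere reaches past rho_i
    term <- 0.5 * (1 / L - 1 / U + 0.25 * (r - sr^2 / r) * (1 / U^2 - 1 / L^2) +
                     0.5 * log(L / U) / r)
    inside <- rho[i] < sr - r  # atom i engulfed by j's scaled sphere
    term[inside] <- term[inside] + (1 / rho[i] - 1 / L[inside])
    I[i] <- sum(term[keep])
  }
  psi <- rho * I
  inv <- 1 / rho - tanh(params$obc_alpha * psi - params$obc_beta * psi^2 +
                          params$obc_gamma * psi^3) / R
  if (any(inv <= 0)) abort("nonpositive effective Born radius")
  1 / inv
}

#' Generalized-Born polar solvation energy
#'
#' Still pairwise form over the group's atoms (self terms included):
#' `E_GB = -1/2 (1/e_in - 1/e_out) k_e sum_ij q_i q_j / f_ij` with
#' `f_ij = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`. Effective radii are
#' computed on the group's atoms alone.
#'
#' @inheritParams born_radii
#' @return `E_GB` in kcal/mol.
#' @export
gb_energy <- function(structure, coords = NULL, group = NULL,
                      params = gb_params()) {
  e <- .gb_pair_matrix(structure, coords, group, params)
  sum(e)
}

# Full symmetric matrix of ordered-pair GB energies (diagonal = self terms);
# sum(.) is the total GB energy, row sums give a symmetric half-split.
.gb_pair_matrix <- function(structure, coords = NULL, group = NULL,
                            params = gb_params()) {
  xyz <- coords %||% coords(structure)
  idx <- atom_group(structure, group)
  if (!length(idx)) return(matrix(0, 0, 0))
  q <- structure$atoms$charge[idx]
  Reff <- born_radii(structure, xyz, params, idx)
  P <- xyz[idx, , drop = FALSE]
  r2 <- as.matrix(stats::dist(P))^2
  RR <- outer(Reff, Reff)
  f <- sqrt(r2 + RR * exp(-r2 / (4 * RR)))
  tau <- 1 / params$interior_dielectric - 1 / params$exterior_dielectric
  -0.5 * tau * .const$coulomb * outer(q, q) / f
}

# Deterministic unit sphere sampling (golden-spiral / Fibonacci lattice).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples `sasa_points` points on each atom's solvent-expanded sphere
#' (intrinsic Born radius + probe) and counts those not buried inside any
#' neighbour's expanded sphere.
#'
#' @param structure A [bs_structure()].
#' @param coords Frame coordinates (default: the structure's own).
#' @param group Atom subset treated as the solute (default: all atoms).
#' @param probe_radius Solvent probe radius, A.
#' @param n_points Sphere sample count per atom.
#' @return List with `total` (A^2) and `per_atom` tibble (`atom`, `area`).
#' @export
sasa <- function(structure, coords = NULL, group = NULL, probe_radius = 1.4,
                 n_points = 960L) {
  xyz <- coords %||% coords(structure)
  idx <- atom_group(structure, group)
  P <- xyz[idx, , drop = FALSE]
  rad <- structure$atoms$gb_radius[idx] + probe_radius
  n <- length(idx)
  sp <- .sphere_points(n_points)
  area <- numeric(n)
  if (n == 1) {
    area <- 4 * pi * rad^2
  } else {
    dm <- as.matrix(stats::dist(P))
    for (i in seq_len(n)) {
      nb <- which(dm[i, ] < rad[i] + rad & seq_len(n) != i)
      pts <- sweep(sp * rad[i], 2, P[i, ], "+")
      exposed <- rep(TRUE, n_points)
      for (j in nb) {
        d2 <- (pts[, 1] - P[j, 1])^2 + (pts[, 2] - P[j, 2])^2 +
          (pts[, 3] - P[j, 3])^2
        exposed <- exposed & d2 > rad[j]^2
        if (!any(exposed)) break
      }
      area[i] <- 4 * pi * rad[i]^2 * sum(exposed) / n_points
    }
  }
  list(total = sum(area), per_atom = tibble(atom = idx, area = area))
}
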