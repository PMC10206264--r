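# Shared fixtures, built in code. All seeded and cheap; heavier fixtures are
# memoized per test run.

fix_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fix_env[[key]])) fix_env[[key]] <- force(expr)
  fix_env[[key]]
}

# small complex: 8 residues x 6 atoms + 6-atom ligand = 54 atoms
small_spec <- function(n_frames = 50, seed = 7, ...) {
  synthetic_spec(n_receptor_residues = 8, n_ligand_atoms = 6,
                 n_frames = n_frames, seed = seed, ...)
}

small_complex <- function() memo("small_complex", generate_complex(small_spec()))

# atom indices of residue `i`'s backbone N / amide H in the generated chain
res_atom <- function(i, which = c("N", "H", "CA", "C", "O", "CB")) {
  which <- match.arg(which)
  (i - 1L) * 6L + match(which, c("N", "H", "CA", "C", "O", "CB"))
}

# fast GB/SASA parameters for tests
fast_params <- function(...) gb_params(sasa_points = 240L, ...)

# a single Born ion (one atom, charge +1) as a complex-free structure
born_ion <- function(radius = 1.5, charge = 1) {
  at <- tibble::tibble(
    serial = 1L, name = "ION", element = "N", residue_name = "ION",
    residue_index = 1L, chain_id = "A", x = 0, y = 0, z = 0,
    charge = charge, lj_sigma = 3, lj_epsilon = 0.1, mass = 14,
    gb_radius = radius, is_backbone = FALSE)
  bs_structure(at, groups = list(receptor = integer(), ligand = 1L))
}

# free-standing structure from a coordinate matrix (carbon atoms)
xyz_structure <- function(xyz, charge = 0, gb_radius = 1.7) {
  n <- nrow(xyz)
  at <- tibble::tibble(
    serial = seq_len(n), name = paste0("C", seq_len(n)), element = "C",
    residue_name = "XXX", residue_index = seq_len(n), chain_id = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charge, n), lj_sigma = 3.4, lj_epsilon = 0.086,
    mass = 12.011, gb_radius = rep_len(gb_radius, n), is_backbone = FALSE)
  bs_structure(at)
}

# independent quaternion-parameterized RMSD minimizer (oracle for Kabsch):
# coarse random-quaternion scan + Nelder-Mead refinement of the best starts.
oracle_min_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj <- function(q) sqrt(mean(rowSums((A %*% t(rot(q)) - B)^2)))
  withr::with_seed(99, {
    starts <- matrix(stats::rnorm(4 * 400), ncol = 4)
  })
  vals <- apply(starts, 1, obj)
  best <- starts[order(vals)[1:5], , drop = FALSE]
  mins <- apply(best, 1, function(q0) {
    stats::optim(q0, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))$value
  })
  min(mins)
}

# two-basin trajectory for clustering: basin B displaces the last two residues
two_basin_traj <- function(n_a = 80, n_b = 20, jitter = 0.05, seed = 21) {
  st <- small_complex()
  ref <- coords(st)
  alt <- ref
  tailres <- which(st$atoms$residue_index >= 7 & st$atoms$chain_id == "A")
  alt[tailres, 3] <- alt[tailres, 3] + 4.0
  withr::with_seed(seed, {
    nf <- n_a + n_b
    arr <- array(NA_real_, c(nf, nrow(ref), 3))
    lab <- rep(c(1L, 2L), c(n_a, n_b))
    for (f in seq_len(nf)) {
      base <- if (lab[f] == 1L) ref else alt
      arr[f, , ] <- base + matrix(stats::rnorm(length(ref), 0, jitter),
                                  ncol = 3)
    }
    list(traj = bs_trajectory(st, arr), labels = lab)
  })
}
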