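test_that("molecular-mechanics pair terms match their closed forms", {
  # two atoms at the LJ minimum separation: E_vdW = -eps_ij
  sig <- 3.4; eps <- 0.2
  r0 <- 2^(1 / 6) * sig
  at <- tibble::tibble(
    serial = 1:2, name = c("C1", "C2"), element = "C",
    residue_name = c("AAA", "LIG"), residue_index = 1L,
    chain_id = c("A", "L"), x = c(0, r0), y = 0, z = 0,
    charge = 0, lj_sigma = sig, lj_epsilon = eps, mass = 12,
    gb_radius = 1.7, is_backbone = FALSE)
  st <- bs_structure(at, groups = list(receptor = 1L, ligand = 2L))
  mm <- pairwise_mm_terms(st)
  expect_equal(unname(mm["E_vdW"]), -eps, tolerance = 1e-10)
  expect_equal(unname(mm["E_ele"]), 0)

  # +1/-1 charges at 3.32 A: E_ele = -332.0637 / 3.32 = -100.0192...
  at2 <- at
  at2$charge <- c(1, -1)
  at2$x <- c(0, 3.32)
  at2$lj_epsilon <- 0
  st2 <- bs_structure(at2, groups = list(receptor = 1L, ligand = 2L))
  expect_equal(unname(pairwise_mm_terms(st2)["E_ele"]),
               -332.0637 / 3.32, tolerance = 1e-10)

  # empty partner group
  st3 <- bs_structure(at, groups = list(receptor = 1:2, ligand = integer()))
  expect_equal(unname(pairwise_mm_terms(st3)), c(0, 0))

  # clash detection
  at4 <- at
  at4$x <- c(0, 0.3)
  st4 <- bs_structure(at4, groups = list(receptor = 1L, ligand = 2L))
  expect_error(pairwise_mm_terms(st4), "clash")
})

test_that("effective Born radii hit the isolation limit and grow with burial", {
  p <- gb_params()
  ion <- born_ion(radius = 1.6)
  expect_equal(born_radii(ion, params = p), 1.6 - p$offset, tolerance = 1e-12)

  # two-atom pair: decreasing separation never shrinks either radius
  seps <- seq(10, 2, by = -0.5)
  radii <- t(vapply(seps, function(d) {
    st <- xyz_structure(rbind(c(0, 0, 0), c(d, 0, 0)))
    born_radii(st, params = p)
  }, c(0, 0)))
  expect_true(all(diff(radii[, 1]) > -1e-12))
  expect_true(all(diff(radii[, 2]) > -1e-12))

  # generated complex: all radii finite and physically sized
  st <- small_complex()
  r <- born_radii(st, params = p)
  expect_true(all(is.finite(r)))
  expect_true(all(r > 0.8))
})

test_that("GB energy reproduces the Born ion and a brute-force double loop", {
  # analytic Born limit, zero offset so R_eff equals the intrinsic radius
  p0 <- gb_params(offset = 0)
  ion <- born_ion(radius = 1.5, charge = 1)
  analytic <- -0.5 * (1 - 1 / 78.5) * 332.0637 / 1.5
  expect_equal(gb_energy(ion, params = p0), analytic, tolerance = 1e-6 * abs(analytic))

  # with the default offset the self energy uses R - offset, still analytic
  p <- gb_params()
  analytic2 <- -0.5 * (1 - 1 / 78.5) * 332.0637 / (1.5 - p$offset)
  expect_equal(gb_energy(ion, params = p), analytic2, tolerance = 1e-6 * abs(analytic2))

  # zero charges -> zero energy
  st0 <- xyz_structure(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)), charge = 0)
  expect_equal(gb_energy(st0, params = p), 0)

  # three charged atoms vs an explicit double loop over the Still formula
  xyz <- rbind(c(0, 0, 0), c(3.1, 0.4, -0.2), c(1.2, 2.8, 0.7))
  st <- xyz_structure(xyz, charge = c(0.4, -0.7, 0.3))
  Reff <- born_radii(st, params = p)
  q <- st$atoms$charge
  tau <- 1 - 1 / 78.5
  ref <- 0
  for (i in 1:3) for (j in 1:3) {
    r2 <- sum((xyz[i, ] - xyz[j, ])^2)
    f <- sqrt(r2 + Reff[i] * Reff[j] * exp(-r2 / (4 * Reff[i] * Reff[j])))
    ref <- ref - 0.5 * tau * 332.0637 * q[i] * q[j] / f
  }
  expect_equal(gb_energy(st, params = p), ref, tolerance = 1e-10)
})

test_that("Shrake-Rupley areas match spheres, burial and self-convergence", {
  ion <- born_ion(radius = 1.5)
  a <- sasa(ion, probe_radius = 1.4, n_points = 960)$total
  expect_lt(abs(a - 4 * pi * 2.9^2) / (4 * pi * 2.9^2), 0.01)

  # an atom fully buried in a cage of large spheres has zero area
  cage <- rbind(c(0, 0, 0),
                3 * rbind(diag(3), -diag(3),
                          cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), 1) / sqrt(3),
                          cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), -1) / sqrt(3)))
  stc <- xyz_structure(cage, gb_radius = 3.4)
  per <- sasa(stc, probe_radius = 1.4, n_points = 960)$per_atom
  expect_equal(per$area[1], 0)

  # two overlapping spheres: 960 points within 2% of a 10000-point reference
  st2 <- xyz_structure(rbind(c(0, 0, 0), c(2.0, 0, 0)), gb_radius = c(1.7, 1.5))
  lo <- sasa(st2, probe_radius = 1.4, n_points = 960)$total
  hi <- sasa(st2, probe_radius = 1.4, n_points = 10000)$total
  expect_lt(abs(lo - hi) / hi, 0.02)
})

test_that("frame deltas vanish at infinite separation and keep their identities", {
  st <- small_complex()
  p <- fast_params()
  xyz <- coords(st)
  xyz[st$groups$ligand, 3] <- xyz[st$groups$ligand, 3] + 500
  far <- frame_binding_energy(st, xyz, p)
  expect_lt(max(abs(c(far$E_vdW, far$E_ele, far$E_GB, far$E_surf))), 1e-3)

  near <- frame_binding_energy(st, params = p)
  expect_identical(near$E_gas, near$E_vdW + near$E_ele)
  expect_identical(near$E_solv, near$E_GB + near$E_surf)
  # delta E_GB equals the explicit three-evaluation difference
  ref <- gb_energy(st, params = p) -
    gb_energy(st, group = "receptor", params = p) -
    gb_energy(st, group = "ligand", params = p)
  expect_equal(near$E_GB, ref, tolerance = 1e-12)
})

test_that("quasi-harmonic entropy matches the analytic oscillator value", {
  k <- 3; temp <- 300; n_at <- 40
  traj <- generate_harmonic_trajectory(n_at, k, temp, n_frames = 8000, seed = 4)
  est <- quasi_harmonic_entropy(traj, temperature = temp, fit = FALSE,
                                drop_modes = 0)
  # closed form: 3N identical modes with omega = sqrt(k/m)
  kcalmol_J <- 4184 / 6.02214076e23
  k_SI <- k * kcalmol_J / 1e-20
  m_SI <- 12.011 * 1.66053907e-27
  x <- 1.0545718e-34 * sqrt(k_SI / m_SI) / (1.380649e-23 * temp)
  s_mode <- 0.0019872041 * (x / expm1(x) - log1p(-exp(-x)))
  analytic <- temp * 3 * n_at * s_mode
  expect_lt(abs(est - analytic) / analytic, 0.02)

  # duplicating every frame leaves the estimate unchanged
  dup <- bs_trajectory(traj$structure,
                       traj$coords[rep(1:2000, each = 2), , ],
                       seq_len(4000) - 1)
  one <- bs_trajectory(traj$structure,
                       traj$coords[1:2000, , ], seq_len(2000) - 1)
  e_dup <- quasi_harmonic_entropy(dup, fit = FALSE, drop_modes = 0)
  e_one <- quasi_harmonic_entropy(one, fit = FALSE, drop_modes = 0)
  expect_equal(e_dup, e_one, tolerance = 1e-3)
})

test_that("frame-averaged binding energy assembles dG = dH - TdS", {
  s <- small_spec(n_frames = 12)
  traj <- generate_trajectory(small_complex(), s)
  be <- average_binding_energy(traj, params = fast_params(), entropy = -5)
  expect_identical(be$delta_G, be$enthalpy - be$T_delta_S)
  expect_identical(be$enthalpy, be$delta$E_gas + be$delta$E_solv)
  expect_equal(be$T_delta_S, -5)
  expect_equal(be$n_frames_energy, 12)
  td <- tidy(be)
  expect_true(all(c("term", "estimate", "sd") %in% names(td)))
  gl <- glance(be)
  expect_equal(gl$delta_G, be$delta_G)
})

test_that("per-residue subtotals conserve the delta enthalpy every time", {
  s <- synthetic_spec(6, 5, 5, seed = 11)
  st <- generate_complex(s)
  traj <- generate_trajectory(st, s)
  p <- fast_params()
  dec <- decompose_per_residue(traj, params = p)
  be <- average_binding_energy(traj, params = p, entropy = 0)
  expect_lt(abs(sum(dec$d_subtotal) - be$enthalpy), 1e-3)
  expect_equal(dec$sidechain_subtotal + dec$backbone_subtotal,
               dec$d_subtotal, tolerance = 1e-6)
  expect_equal(dec$d_subtotal,
               residue_subtotal(dec$d_vdW, dec$d_ele, dec$d_GB, dec$d_surf))
  expect_identical(dec$is_key, abs(dec$d_subtotal) >= 0.5)
  # ligand pseudo-residue present once, last
  expect_equal(sum(dec$residue_name == "LIG"), 1)
  expect_equal(dec$residue_name[nrow(dec)], "LIG")
})
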