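test_that("superposition is exact on itself and on rigid copies", {
  st <- small_complex()
  xyz <- coords(st)
  expect_equal(superpose(xyz, xyz)$rmsd, 0, tolerance = 1e-10)

  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- sweep(xyz %*% R, 2, c(5, -3, 2), "+")
  fit <- superpose(moved, xyz)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  expect_error(superpose(xyz[1:2, ], xyz[1:2, ]), ">= 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("Kabsch RMSD matches an independent quaternion minimizer", {
  withr::with_seed(31, {
    for (rep in 1:3) {
      A <- matrix(rnorm(30), ncol = 3)
      th <- runif(1, 0, pi)
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
      B <- sweep(A %*% R, 2, rnorm(3), "+") + matrix(rnorm(30, 0, 0.3), ncol = 3)
      expect_equal(superpose(A, B)$rmsd, oracle_min_rmsd(A, B),
                   tolerance = 1e-4)
    }
  })
})

test_that("RMSD series vanishes on constant trajectories and is rigid-motion invariant", {
  st <- small_complex()
  n <- nrow(st$atoms)
  arr <- array(rep(coords(st), each = 20), c(20, n, 3))
  traj <- bs_trajectory(st, arr)
  expect_true(all(rmsd_series(traj)$rmsd < 1e-10))

  # displace frame 10 rigidly: its RMSD must stay 0; a per-atom displacement
  # of one atom gives the analytic RMSD sqrt(d^2 / n)
  arr2 <- arr
  arr2[10, , 1] <- arr2[10, , 1] + 50
  expect_lt(rmsd_series(bs_trajectory(st, arr2))$rmsd[10], 1e-6)
  arr3 <- arr
  arr3[5, 1, ] <- arr3[5, 1, ] + c(3, 0, 0)
  r5 <- rmsd_series(bs_trajectory(st, arr3))$rmsd[5]
  # superposition redistributes part of a single-atom shift; bounded above by
  # the unfitted value and below by a positive fraction of it
  expect_lt(r5, sqrt(9 / n))
  expect_gt(r5, 0.5 * sqrt(9 / n))

  s <- small_spec(n_frames = 15)
  traj4 <- generate_trajectory(st, s)
  base <- rmsd_series(traj4, "receptor")
  arr5 <- traj4$coords
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  for (f in 1:15) {
    arr5[f, , ] <- sweep(matrix(arr5[f, , ], ncol = 3) %*% R, 2, c(7, 8, -9), "+")
  }
  moved <- rmsd_series(bs_trajectory(st, arr5), "receptor")
  expect_equal(moved$rmsd, base$rmsd, tolerance = 1e-8)
})

test_that("RMSF recovers isotropic jitter and flags planted flexible residues", {
  st <- generate_complex(synthetic_spec(20, 4, 2, seed = 2))
  n <- nrow(st$atoms)
  rec <- st$groups$receptor
  withr::with_seed(17, {
    nf <- 5000
    noise <- array(rnorm(nf * n * 3, 0, 0.5), c(nf, n, 3))
  })
  arr <- sweep(noise, c(2, 3), coords(st), "+")
  traj <- bs_trajectory(st, arr)
  rf <- rmsf_per_residue(traj, rec)
  expect_lt(abs(mean(rf$rmsf) - 0.5 * sqrt(3)) / (0.5 * sqrt(3)), 0.05)

  # constant trajectory -> zero
  flat <- bs_trajectory(st, array(rep(coords(st), each = 4), c(4, n, 3)))
  expect_true(all(rmsf_per_residue(flat, rec)$rmsf < 1e-10))

  # residues 10-11 jittered 4x more are the series maximum
  hot <- which(st$atoms$residue_index %in% c(10, 11) & st$atoms$chain_id == "A")
  arr2 <- arr
  arr2[, hot, ] <- sweep(4 * noise[, hot, ], c(2, 3), coords(st)[hot, ], "+")
  rf2 <- rmsf_per_residue(bs_trajectory(st, arr2), rec)
  top2 <- rf2$residue_index[order(-rf2$rmsf)][1:2]
  expect_setequal(top2, c(10, 11))
})

test_that("hydrogen-bond criteria apply strictly at both thresholds", {
  # donor D at origin, H at +1.0x; acceptor placed at controlled d and angle
  build <- function(d, angle_deg) {
    A <- bindsight:::.place_acceptor(c(0, 0, 0), c(1, 0, 0), d, angle_deg)
    at <- tibble::tibble(
      serial = 1:3, name = c("N", "H", "O"), element = c("N", "H", "O"),
      residue_name = c("ALA", "ALA", "LIG"), residue_index = c(1L, 1L, 1L),
      chain_id = c("A", "A", "L"),
      x = c(0, 1, A[1]), y = c(0, 0, A[2]), z = c(0, 0, A[3]),
      charge = 0, lj_sigma = 3, lj_epsilon = 0.1, mass = 14,
      gb_radius = 1.5, is_backbone = FALSE)
    st <- bs_structure(at, bonds = cbind(1L, 2L),
                       groups = list(receptor = 1:2, ligand = 3L))
    bs_trajectory(st, array(rep(coords(st), each = 1), c(1, 3, 3)))
  }
  hb <- detect_hbonds(build(3.2, 150), occupancy_floor = 0)
  expect_equal(hb$occupancy[1], 100)
  hb2 <- detect_hbonds(build(3.6, 170), occupancy_floor = 0)
  expect_equal(hb2$occupancy[1], 0)
  hb3 <- detect_hbonds(build(3.2, 100), occupancy_floor = 0)
  expect_equal(hb3$occupancy[1], 0)
})

test_that("intermolecular hydrogen-bond counts track the planted occupancies", {
  full <- list(
    planted_hbond(res_atom(2, "N"), res_atom(2, "H"), 49L, 1.0),
    planted_hbond(res_atom(4, "N"), res_atom(4, "H"), 52L, 1.0),
    planted_hbond(res_atom(6, "N"), res_atom(6, "H"), 55L, 1.0))
  s <- synthetic_spec(8, 8, 80, planted_hbonds = full, seed = 19)
  st <- generate_complex(s)
  traj <- generate_trajectory(st, s)
  cs <- hbond_count_series(traj)
  expect_equal(attr(cs, "mean"), 3)
  expect_equal(attr(cs, "sd"), 0)

  half <- list(
    planted_hbond(res_atom(2, "N"), res_atom(2, "H"), 49L, 1.0),
    planted_hbond(res_atom(4, "N"), res_atom(4, "H"), 52L, 0.5))
  n <- 1000
  s2 <- synthetic_spec(8, 8, n, planted_hbonds = half, seed = 23)
  traj2 <- generate_trajectory(generate_complex(s2), s2)
  cs2 <- hbond_count_series(traj2)
  ci <- 1 + stats::qbinom(c(0.005, 0.995), n, 0.5) / n
  expect_gte(attr(cs2, "mean"), ci[1])
  expect_lte(attr(cs2, "mean"), ci[2])
})

test_that("geometry monitors return exact angles for planted geometries", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),            # collinear
               c(0, 5, 0), c(1, 5, 0), c(0.5, 5 + sqrt(3) / 2, 0)) # equilateral
  st <- xyz_structure(xyz)
  traj <- bs_trajectory(st, array(rep(xyz, each = 2), c(2, 6, 3)))
  mon <- monitor_geometry(traj, list(line = c(1, 2, 3), tri = c(4, 6, 5),
                                     d = c(1, 2)))
  s <- attr(mon, "summary")
  expect_equal(s$mean[s$probe == "line"], 180, tolerance = 1e-8)
  expect_equal(s$mean[s$probe == "tri"], 60, tolerance = 1e-8)
  expect_equal(s$mean[s$probe == "d"], 1, tolerance = 1e-10)
  expect_error(monitor_geometry(traj, list(bad = c(1, 99))), "invalid")
})

test_that("clustering recovers a planted 80/20 conformational mix with medoids in-basin", {
  tb <- two_basin_traj(80, 20)
  cl <- cluster_frames(tb$traj, "receptor", 2)
  expect_equal(cl$clusters$percent, c(80, 20), tolerance = 0.025)
  expect_equal(sum(cl$clusters$percent), 100, tolerance = 1e-6)
  # medoid frames must carry the label of their own cluster's basin
  med <- cl$clusters$representative_frame
  expect_equal(tb$labels[med], c(1L, 2L))
  # representative belongs to its cluster
  expect_equal(cl$labels[match(med, tb$traj |> n_frames() |> seq_len())],
               cl$clusters$cluster)
})

test_that("single-cluster and degenerate clustering behave sanely", {
  st <- small_complex()
  n <- nrow(st$atoms)
  flat <- bs_trajectory(st, array(rep(coords(st), each = 6), c(6, n, 3)))
  cl1 <- cluster_frames(flat, NULL, 1)
  expect_equal(cl1$clusters$percent, 100)
  cl2 <- cluster_frames(flat, NULL, 3)
  expect_equal(sum(cl2$clusters$n_frames), 6)
  expect_error(cluster_frames(flat, NULL, 10), "exceeds")
})

test_that("occupancy estimation is unbiased across seeds", {
  target <- 0.6
  occ <- vapply(1:20, function(sd) {
    s <- synthetic_spec(4, 4, 400, planted_hbonds = list(
      planted_hbond(res_atom(2, "N"), res_atom(2, "H"), 25L, target)),
      seed = 100 + sd)
    traj <- generate_trajectory(generate_complex(s), s)
    hb <- detect_hbonds(traj, occupancy_floor = 0)
    hb$occupancy[hb$donor_index == res_atom(2, "N") & hb$acceptor_index == 25L]
  }, 0)
  expect_lt(abs(mean(occ) - 100 * target), 1)
})
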