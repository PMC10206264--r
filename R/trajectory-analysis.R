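#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between the
#' `atom_subset` rows of `mobile` and `reference`. The transform applies to the
#' full mobile coordinate set as `mobile %*% rotation + translation`.
#'
#' @param mobile,reference `n x 3` coordinate matrices on the same atom roster.
#' @param atom_subset Atom indices used for the fit (default: all). Must hold
#'   at least 3 non-collinear atoms.
#' @return List with `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` (A, over the subset) and `coords` (the transformed mobile set).
#' @export
superpose <- function(mobile, reference, atom_subset = NULL) {
  if (is.null(atom_subset)) atom_subset <- seq_len(nrow(mobile))
  if (length(atom_subset) < 3) abort("superposition needs >= 3 atoms")
  A <- mobile[atom_subset, , drop = FALSE]
  B <- reference[atom_subset, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv <- svd(crossprod(A0, B0))  # 3x3 covariance
  if (sv$d[2] < 1e-10) abort("degenerate (collinear) atom subset")
  sgn <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, sgn))
  R <- sv$u %*% D %*% t(sv$v)
  trans <- cb - as.vector(ca %*% R)
  fitted <- sweep(mobile %*% R, 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((fitted[atom_subset, , drop = FALSE] - B)^2)))
  list(rotation = R, translation = trans, rmsd = rmsd, coords = fitted)
}

#' Per-frame RMSD series
#'
#' Each frame is superposed onto the reference frame over `atom_subset` before
#' the RMSD (over the same subset) is taken, so the series is invariant to any
#' global rigid motion of the frames.
#'
#' @param traj A [bs_trajectory()].
#' @param atom_subset Atom indices or group name (default: all atoms).
#' @param reference_frame Reference frame index (1-based).
#' @return Tibble with `frame`, `time`, `rmsd` (A).
#' @export
rmsd_series <- function(traj, atom_subset = NULL, reference_frame = 1L) {
  sub <- atom_group(traj$structure, atom_subset)
  ref <- frame_coords(traj, reference_frame)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    superpose(frame_coords(traj, f), ref, sub)$rmsd
  }, 0)
  tibble(frame = seq_len(n_frames(traj)), time = traj$times, rmsd = vals)
}

# Iterated mean-structure fit (2 passes): returns frames x atoms x 3 array
# superposed onto the converged mean over `sub`.
.fit_to_mean <- function(traj, sub, passes = 2L) {
  arr <- traj$coords
  nf <- dim(arr)[1]
  ref <- matrix(arr[1, , ], ncol = 3)
  for (p in seq_len(passes)) {
    for (f in seq_len(nf)) {
      arr[f, , ] <- superpose(matrix(arr[f, , ], ncol = 3), ref, sub)$coords
    }
    ref <- apply(arr, c(2, 3), mean)
  }
  arr
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are iteratively superposed onto their mean structure (two passes)
#' over `atom_subset`; the per-atom RMSF `sqrt(<|r - <r>|^2>)` is then averaged
#' over the selected atoms of each residue.
#'
#' @param traj A [bs_trajectory()].
#' @param atom_subset Atom indices or group name defining both the fit and the
#'   reported atoms (e.g. the CA set). Default: all atoms.
#' @return Tibble with `chain_id`, `residue_index`, `residue_name`, `rmsf` (A).
#' @export
rmsf_per_residue <- function(traj, atom_subset = NULL) {
  sub <- atom_group(traj$structure, atom_subset)
  if (!length(sub)) abort("empty atom subset")
  arr <- .fit_to_mean(traj, sub)
  mean_xyz <- apply(arr, c(2, 3), mean)
  dev2 <- sweep(arr, c(2, 3), mean_xyz)^2
  msf <- apply(dev2, 2, sum) / dim(arr)[1]  # per-atom mean squared fluctuation
  at <- traj$structure$atoms
  tibble(atom = sub, rmsf = sqrt(msf[sub]),
         chain_id = at$chain_id[sub],
         residue_index = at$residue_index[sub],
         residue_name = at$residue_name[sub]) |>
    group_by(.data$chain_id, .data$residue_index, .data$residue_name) |>
    summarise(rmsf = mean(.data$rmsf), .groups = "drop") |>
    arrange(.data$chain_id, .data$residue_index)
}

#' Hydrogen-bond geometric criteria
#'
#' A donor-H...acceptor triple counts as bonded in a frame iff the
#' donor-acceptor distance is strictly below `max_donor_acceptor_distance` and
#' the acceptor-H-donor angle (vertex at the hydrogen) is strictly above
#' `min_angle_at_hydrogen`.
#'
#' @param max_donor_acceptor_distance A (default 3.5).
#' @param min_angle_at_hydrogen Degrees (default 120).
#' @return A `bs_hbond_criteria` list.
#' @export
hbond_criteria <- function(max_donor_acceptor_distance = 3.5,
                           min_angle_at_hydrogen = 120) {
  if (max_donor_acceptor_distance <= 0) abort("distance cutoff must be positive")
  if (min_angle_at_hydrogen <= 0 || min_angle_at_hydrogen >= 180) {
    abort("angle cutoff must be in (0, 180)")
  }
  structure(list(max_donor_acceptor_distance = max_donor_acceptor_distance,
                 min_angle_at_hydrogen = min_angle_at_hydrogen),
            class = "bs_hbond_criteria")
}

# Donor atoms (N/O/S with an attached H) and their hydrogens. Uses the bond
# table; falls back to any H within 1.2 A in the reference coordinates.
.donor_hydrogens <- function(structure) {
  at <- structure$atoms
  is_h <- at$element == "H"
  cand <- if ("is_donor" %in% names(at) && !all(is.na(at$is_donor))) {
    which(!is.na(at$is_donor) & at$is_donor)
  } else {
    which(at$element %in% c("N", "O", "S"))
  }
  pairs <- NULL
  if (nrow(structure$bonds)) {
    b <- structure$bonds
    hb1 <- b[b[, 1] %in% cand & is_h[b[, 2]], , drop = FALSE]
    hb2 <- b[b[, 2] %in% cand & is_h[b[, 1]], c(2, 1), drop = FALSE]
    pairs <- rbind(hb1, hb2)
  }
  if (is.null(pairs) || !nrow(pairs)) {
    xyz <- coords(structure)
    hs <- which(is_h)
    out <- list()
    for (d in cand) {
      for (h in hs) {
        if (sqrt(sum((xyz[d, ] - xyz[h, ])^2)) < 1.2) {
          out[[length(out) + 1L]] <- c(d, h)
        }
      }
    }
    pairs <- if (length(out)) do.call(rbind, out) else matrix(integer(), ncol = 2)
  }
  pairs
}

.acceptor_atoms <- function(structure) {
  at <- structure$atoms
  if ("is_acceptor" %in% names(at) && !all(is.na(at$is_acceptor))) {
    which(!is.na(at$is_acceptor) & at$is_acceptor)
  } else {
    which(at$element %in% c("N", "O"))
  }
}

.angle_at <- function(v1, v2) {
  # angle between row-vectors v1 and v2 (matrices), degrees
  num <- rowSums(v1 * v2)
  den <- sqrt(rowSums(v1^2) * rowSums(v2^2))
  acos(pmin(pmax(num / den, -1), 1)) * 180 / pi
}

#' Detect hydrogen bonds and their occupancies
#'
#' Scans donor-H...acceptor triples over all frames and reports, per triple,
#' the percentage of frames satisfying the geometric criteria plus the mean
#' and sd of the donor-acceptor distance and the angle at the hydrogen over
#' all frames.
#'
#' @param traj A [bs_trajectory()].
#' @param criteria A [hbond_criteria()].
#' @param donors Candidate donor atom indices (default: N/O/S atoms with an
#'   attached hydrogen, or topology `is_donor` flags when present).
#' @param acceptors Candidate acceptor indices (default: N/O atoms, or
#'   topology `is_acceptor` flags).
#' @param intermolecular If `TRUE` keep only donor/acceptor pairs crossing the
#'   receptor/ligand boundary.
#' @param occupancy_floor Reporting floor in percent; triples below it are
#'   dropped (default 5).
#' @return Tibble sorted by descending occupancy with donor/hydrogen/acceptor
#'   identities, `occupancy` (percent), `mean_distance`, `sd_distance` (A),
#'   `mean_angle`, `sd_angle` (degrees) and a `flags` list-column of per-frame
#'   logicals.
#' @export
detect_hbonds <- function(traj, criteria = hbond_criteria(), donors = NULL,
                          acceptors = NULL, intermolecular = TRUE,
                          occupancy_floor = 5) {
  st <- traj$structure
  dh <- .donor_hydrogens(st)
  if (!is.null(donors)) dh <- dh[dh[, 1] %in% donors, , drop = FALSE]
  acc <- acceptors %||% .acceptor_atoms(st)
  if (!nrow(dh) || !length(acc)) return(.empty_hbond_table())
  lig <- st$groups$ligand %||% integer()
  in_lig <- seq_len(nrow(st$atoms)) %in% lig
  arr <- traj$coords
  nf <- dim(arr)[1]
  at <- st$atoms
  rows <- list()
  for (r in seq_len(nrow(dh))) {
    d <- dh[r, 1]; h <- dh[r, 2]
    for (a in acc) {
      if (a == d || a == h) next
      if (intermolecular && in_lig[a] == in_lig[d]) next
      Dm <- matrix(arr[, d, ], ncol = 3); Hm <- matrix(arr[, h, ], ncol = 3)
      Am <- matrix(arr[, a, ], ncol = 3)
      dist_da <- sqrt(rowSums((Dm - Am)^2))
      ang <- .angle_at(Dm - Hm, Am - Hm)
      flags <- dist_da < criteria$max_donor_acceptor_distance &
        ang > criteria$min_angle_at_hydrogen
      occ <- 100 * sum(flags) / nf
      rows[[length(rows) + 1L]] <- tibble(
        donor = .atom_label(at, d), hydrogen = .atom_label(at, h),
        acceptor = .atom_label(at, a),
        donor_index = d, hydrogen_index = h, acceptor_index = a,
        occupancy = occ,
        mean_distance = mean(dist_da), sd_distance = sd(dist_da),
        mean_angle = mean(ang), sd_angle = sd(ang),
        flags = list(flags))
    }
  }
  out <- bind_rows(rows)
  if (!nrow(out)) return(.empty_hbond_table())
  out |>
    filter(.data$occupancy >= occupancy_floor) |>
    arrange(desc(.data$occupancy))
}

.atom_label <- function(atoms, i) {
  paste0(atoms$residue_name[i], atoms$residue_index[i], "@", atoms$name[i])
}

.empty_hbond_table <- function() {
  tibble(donor = character(), hydrogen = character(), acceptor = character(),
         donor_index = integer(), hydrogen_index = integer(),
         acceptor_index = integer(), occupancy = double(),
         mean_distance = double(), sd_distance = double(),
         mean_angle = double(), sd_angle = double(), flags = list())
}

#' Per-frame intermolecular hydrogen-bond count
#'
#' Counts, per frame, distinct donor-acceptor pairs crossing the
#' receptor/ligand boundary that satisfy the criteria (a pair with several
#' hydrogens counts once).
#'
#' @inheritParams detect_hbonds
#' @return Tibble with `frame`, `time`, `n_hbonds`; the mean and sd over
#'   frames are attached as attributes `"mean"` and `"sd"`.
#' @export
hbond_count_series <- function(traj, criteria = hbond_criteria()) {
  hb <- detect_hbonds(traj, criteria, intermolecular = TRUE, occupancy_floor = 0)
  nf <- n_frames(traj)
  counts <- integer(nf)
  if (nrow(hb)) {
    pair_key <- paste(hb$donor_index, hb$acceptor_index)
    for (k in unique(pair_key)) {
      fl <- Reduce(`|`, hb$flags[pair_key == k])
      counts <- counts + as.integer(fl)
    }
  }
  out <- tibble(frame = seq_len(nf), time = traj$times, n_hbonds = counts)
  attr(out, "mean") <- mean(counts)
  attr(out, "sd") <- sd(counts)
  out
}

#' Monitor distances and angles along a trajectory
#'
#' @param traj A [bs_trajectory()].
#' @param probes Named list; each element an atom index pair (distance, A) or
#'   triple (angle at the middle atom, degrees).
#' @return Long tibble with `probe`, `kind`, `frame`, `time`, `value`, plus a
#'   per-probe `summary` tibble (`mean`, `sd`) as attribute `"summary"`.
#' @export
monitor_geometry <- function(traj, probes) {
  if (is.null(names(probes))) names(probes) <- paste0("probe", seq_along(probes))
  arr <- traj$coords
  n_at <- dim(arr)[2]
  rows <- purrr::imap(probes, function(p, nm) {
    p <- as.integer(p)
    if (any(p < 1 | p > n_at)) abort(paste0("probe '", nm, "': invalid atom index"))
    if (length(p) == 2) {
      v <- sqrt(rowSums((matrix(arr[, p[1], ], ncol = 3) -
                           matrix(arr[, p[2], ], ncol = 3))^2))
      kind <- "distance"
    } else if (length(p) == 3) {
      v <- .angle_at(matrix(arr[, p[1], ], ncol = 3) - matrix(arr[, p[2], ], ncol = 3),
                     matrix(arr[, p[3], ], ncol = 3) - matrix(arr[, p[2], ], ncol = 3))
      kind <- "angle"
    } else {
      abort(paste0("probe '", nm, "' must have 2 or 3 atoms"))
    }
    tibble(probe = nm, kind = kind, frame = seq_len(length(v)),
           time = traj$times, value = v)
  })
  out <- bind_rows(rows)
  attr(out, "summary") <- out |>
    group_by(.data$probe, .data$kind) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value), .groups = "drop")
  out
}

#' Cluster trajectory frames and extract medoid representatives
#'
#' Average-linkage hierarchical clustering on the pairwise RMSD matrix over
#' `atom_subset` (frames superposed pairwise), cut to `n_clusters`. Each
#' cluster's representative is its medoid: the member frame minimizing the
#' summed RMSD to all other members.
#'
#' @param traj A [bs_trajectory()].
#' @param atom_subset Atom indices or group name for the RMSD (default: all).
#' @param n_clusters Number of clusters.
#' @param stride Frame stride for the pairwise matrix.
#' @return A `bs_clusters` object: `labels` (per analyzed frame), `clusters`
#'   tibble (`cluster`, `n_frames`, `percent`, `representative_frame` in the
#'   original frame numbering), `frames` (analyzed frame indices).
#' @export
cluster_frames <- function(traj, atom_subset = NULL, n_clusters = 2L, stride = 1L) {
  sub <- atom_group(traj$structure, atom_subset)
  frames <- seq(1L, n_frames(traj), by = as.integer(stride))
  nf <- length(frames)
  if (n_clusters > nf) abort("n_clusters exceeds number of analyzed frames")
  mats <- lapply(frames, function(f) frame_coords(traj, f))
  dm <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in seq(i + 1, nf)) {
      dm[i, j] <- dm[j, i] <- superpose(mats[[i]], mats[[j]], sub)$rmsd
    }
  }
  labels <- if (n_clusters == 1L) rep(1L, nf) else {
    cutree(hclust(as.dist(dm), method = "average"), k = n_clusters)
  }
  # relabel clusters by decreasing population (ties: first occurrence)
  ord <- order(-tabulate(labels, n_clusters), match(seq_len(n_clusters), labels))
  labels <- match(labels, ord)
  cl <- purrr::map_dfr(seq_len(n_clusters), function(k) {
    members <- which(labels == k)
    med <- members[which.min(rowSums(dm[members, members, drop = FALSE]))]
    tibble(cluster = k, n_frames = length(members),
           percent = 100 * length(members) / nf,
           representative_frame = frames[med])
  })
  structure(list(labels = labels, clusters = cl, frames = frames,
                 atom_subset = sub),
            class = "bs_clusters")
}

#' @export
print.bs_clusters <- function(x, ...) {
  cat("<bs_clusters> ", nrow(x$clusters), " clusters over ",
      length(x$frames), " frames\n", sep = "")
  print(x$clusters)
  invisible(x)
}

#' @rdname cluster_frames
#' @param x A `bs_clusters` object.
#' @param ... Unused.
#' @export
tidy.bs_clusters <- function(x, ...) x$clusters

#' Extract medoid receptor structures as an ensemble
#'
#' Pulls the representative (medoid) frame of each cluster and returns the
#' receptor-only structures, labelled `Cluster1`, `Cluster2`, ... in
#' population order, together with cluster provenance.
#'
#' @param traj The clustered [bs_trajectory()].
#' @param clusters A `bs_clusters` from [cluster_frames()].
#' @param group Atom group to extract (default `"receptor"`).
#' @return A `bs_ensemble`: list of `members` (named [bs_structure()]s) and
#'   `provenance` tibble.
#' @export
receptor_ensemble <- function(traj, clusters, group = "receptor") {
  idx <- atom_group(traj$structure, group)
  members <- list()
  for (k in seq_len(nrow(clusters$clusters))) {
    f <- clusters$clusters$representative_frame[k]
    xyz <- frame_coords(traj, f)
    at <- traj$structure$atoms[idx, ]
    at$x <- xyz[idx, 1]; at$y <- xyz[idx, 2]; at$z <- xyz[idx, 3]
    at$serial <- seq_len(nrow(at))
    members[[paste0("Cluster", k)]] <-
      bs_structure(at, groups = list(receptor = seq_len(nrow(at)),
                                     ligand = integer()))
  }
  structure(list(members = members, provenance = clusters$clusters),
            class = "bs_ensemble")
}
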