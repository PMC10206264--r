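fixed_scorer <- function(tab) {
  function(compound, member_label, member_structure) {
    v <- tab[[compound$name]][[member_label]]
    if (is.null(v)) NA_real_ else v
  }
}

test_that("aggregation takes the minimum over successful members", {
  ens <- list(members = list(Cluster1 = NULL, Cluster2 = NULL))
  scr <- fixed_scorer(list(X = list(Cluster1 = -9.2, Cluster2 = -10.1)))
  rec <- score_compound(tibble::tibble(name = "X"), ens, scr)
  expect_equal(rec$aggregate, -10.1)

  ens1 <- list(members = list(Only = NULL))
  scr1 <- fixed_scorer(list(X = list(Only = -7.7)))
  expect_equal(score_compound(tibble::tibble(name = "X"), ens1, scr1)$aggregate,
               -7.7)

  # partial failure recorded, total failure errors
  scr2 <- fixed_scorer(list(X = list(Cluster1 = -8.0)))
  rec2 <- score_compound(tibble::tibble(name = "X"), ens, scr2)
  expect_equal(rec2$aggregate, -8.0)
  expect_equal(rec2$failed_members, "Cluster2")
  scr3 <- fixed_scorer(list())
  expect_error(score_compound(tibble::tibble(name = "X"), ens, scr3), "every")
})

test_that("the packaged score table reproduces the printed docking aggregates", {
  scorer <- reference_one_region_scorer()
  ens <- list(members = list(ensemble = NULL))
  get <- function(nm) score_compound(tibble::tibble(name = nm), ens, scorer)$aggregate
  expect_equal(get("abemaciclib"), -9.46)
  expect_equal(get("R1f"), -10.03)
  expect_equal(get("R3e"), -10.39)
  expect_equal(get("R4a"), -10.31)
})

test_that("the surrogate scorer is deterministic and prefers the planted pose", {
  st <- small_complex()
  p <- fast_params()
  s1 <- surrogate_score(st, p)
  s2 <- surrogate_score(st, p)
  expect_identical(s1, s2)

  # ligand at 500 A: score ~ 0
  far <- st
  far$atoms$z[far$groups$ligand] <- far$atoms$z[far$groups$ligand] + 500
  expect_lt(abs(surrogate_score(far, p)), 1e-3)

  # displacing the ligand 2 A off its pocket pose worsens the score
  for (shift in list(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))) {
    moved <- st
    moved$atoms[moved$groups$ligand, c("x", "y", "z")] <-
      sweep(as.matrix(moved$atoms[moved$groups$ligand, c("x", "y", "z")]),
            2, shift, "+")
    expect_gt(surrogate_score(moved, p), s1)
  }

  # clash is a declared failure, not an error
  clash <- st
  i <- clash$groups$ligand[1]
  clash$atoms[i, c("x", "y", "z")] <-
    clash$atoms[clash$groups$receptor[1], c("x", "y", "z")] + 0.1
  expect_true(is.na(surrogate_score(clash, p)))
})

test_that("ranking sorts ascending with lexical ties and thresholds the shortlist", {
  rec <- tibble::tibble(name = c("B", "A", "C"),
                        aggregate = c(-10.03, -9.78, -9.46))
  rk <- rank_and_shortlist(rec, -10.0)
  expect_equal(rk$name, c("B", "A", "C"))
  expect_equal(sum(rk$shortlisted), 1)

  expect_equal(nrow(rank_and_shortlist(rec[0, ], -10)), 0)

  tie <- tibble::tibble(name = c("Z", "M", "A"), aggregate = -9.5)
  expect_equal(rank_and_shortlist(tie, -10)$name, c("A", "M", "Z"))
})

test_that("score tables load, reject duplicates and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- tibble::tibble(compound = c("X", "X"), member = c("C1", "C2"),
                        score = c(-9.1, -10.2))
  readr::write_tsv(tab, f)
  scr <- load_score_table(f)
  expect_equal(scr(tibble::tibble(name = "X"), "C2", NULL), -10.2)
  expect_true(is.na(scr(tibble::tibble(name = "Y"), "C1", NULL)))
  expect_equal(attr(scr, "table")$score, tab$score)

  readr::write_tsv(dplyr::bind_rows(tab, tab[1, ]), f)
  expect_error(load_score_table(f), "duplicate")
})

test_that("min aggregation is permutation-invariant and monotone in members", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      scores <- round(stats::rnorm(4, -9.5, 0.8), 2)
      names(scores) <- paste0("M", 1:4)
      tab <- list(X = as.list(scores))
      perm <- sample(names(scores))
      ens_a <- list(members = setNames(vector("list", 4), names(scores)))
      ens_b <- list(members = setNames(vector("list", 4), perm))
      scr <- fixed_scorer(tab)
      agg_a <- score_compound(tibble::tibble(name = "X"), ens_a, scr)$aggregate
      agg_b <- score_compound(tibble::tibble(name = "X"), ens_b, scr)$aggregate
      expect_identical(agg_a, agg_b)
      # adding a member can only lower or keep the aggregate
      tab5 <- tab
      tab5$X$M5 <- round(stats::rnorm(1, -9.5, 0.8), 2)
      ens5 <- list(members = setNames(vector("list", 5), paste0("M", 1:5)))
      agg5 <- score_compound(tibble::tibble(name = "X"), ens5,
                             fixed_scorer(tab5))$aggregate
      expect_lte(agg5, agg_a)
    }
  })
})

test_that("ranking is stable across shuffles of the input order", {
  withr::with_seed(57, {
    rec <- tibble::tibble(name = sprintf("C%04d", 1:30),
                          aggregate = round(stats::rnorm(30, -9.5, 0.6), 2))
    ref <- rank_and_shortlist(rec)
    for (rep in 1:20) {
      shuf <- rec[sample(nrow(rec)), ]
      expect_identical(rank_and_shortlist(shuf), ref)
    }
  })
})
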