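lib_fixture <- function() memo("design_lib", read_design_library())

toy_libs <- function(n_per_region = 3) {
  lapply(setNames(paste0("R", 1:4), paste0("R", 1:4)), function(r) {
    group_library(r, tibble::tibble(
      label = paste0(r, letters[seq_len(n_per_region)]),
      smiles = c("C", "CCC", "CCCC")[seq_len(n_per_region)],
      description = "alkyl"))
  })
}

test_that("one-region enumeration counts and de-duplicates against the base", {
  sc <- lib_fixture()$scaffold
  libs <- toy_libs()
  one <- enumerate_one_region(sc, libs)
  expect_equal(nrow(one), 12)  # 4 regions x 3 entries, none equal to base

  # an entry equal to the base group is excluded
  libs2 <- libs
  libs2$R2 <- group_library("R2", tibble::tibble(
    label = c("R2a", "R2b"), smiles = c("F", "C"), description = ""))
  one2 <- enumerate_one_region(sc, libs2)
  expect_equal(nrow(one2), 12 - 3 + 1)  # R2: only the non-base entry remains
  expect_false("R2a" %in% one2$name)
})

test_that("the shipped library yields the 42-compound one-region set", {
  lib <- lib_fixture()
  one <- enumerate_one_region(lib$scaffold, lib$one_region)
  expect_equal(nrow(one), 42)
  expect_equal(anyDuplicated(one$name), 0)
})

test_that("top-group selection ranks by score with library-order ties", {
  lib <- lib_fixture()
  one <- enumerate_one_region(lib$scaffold, lib$one_region)
  scorer <- reference_one_region_scorer()
  ens <- list(members = list(ensemble = NULL))
  one$aggregate_score <- score_compounds(one, ens, scorer)$aggregate
  red <- select_top_groups(one, lib$one_region, lib$scaffold,
                           base_score = -9.46, per_region = 3)
  expect_setequal(red$R3$entries$label, c("R3e", "R3f", "R3i"))

  red1 <- select_top_groups(one, lib$one_region, lib$scaffold,
                            base_score = -9.46, per_region = 1)
  expect_equal(red1$R3$entries$label, "R3e")

  # exact tie: R1a and R1b both score -9.31; the earlier library entry wins
  red2 <- select_top_groups(one, lib$one_region, lib$scaffold,
                            base_score = -99, per_region = 5)
  r1 <- red2$R1$entries$label
  expect_equal(r1[1], "R1-base")   # injected base outranks everything
  expect_equal(r1[5], "R1a")       # beats the tied R1b by library order

  expect_error(
    select_top_groups(dplyr::mutate(one, aggregate_score = NA_real_),
                      lib$one_region, lib$scaffold, -9.46), "scored")
})

test_that("cross-combination is exhaustive, uniquely named and canonical", {
  lib <- lib_fixture()
  comb <- combine_regions(lib$scaffold, lib$combination)
  expect_equal(nrow(comb), 81)
  expect_equal(anyDuplicated(comb$name), 0)
  expect_equal(length(unique(comb$smiles)), 81)
  # naming is bijective with the group choice
  for (i in c(1, 41, 81)) {
    parsed <- parse_compound_name(comb$name[i])
    expect_equal(parsed$choice, comb$choice[[i]])
  }
  expect_equal(comb$name[1], "C1111")

  # 1x1x1x1 product
  single <- lapply(lib$combination, function(l) {
    group_library(l$region, l$entries[1, ])
  })
  c1 <- combine_regions(lib$scaffold, single)
  expect_equal(nrow(c1), 1)
  expect_equal(c1$name, "C1111")
})

test_that("variant edits rename, stay valid and consume their pattern", {
  lib <- lib_fixture()
  comb <- combine_regions(lib$scaffold, lib$combination)
  c2213 <- comb[comb$name == "C2213", ]
  va <- apply_variant(c2213, lib$variants[[1]])
  expect_equal(va$name, "C2213-A")
  expect_equal(heavy_atom_count(va$smiles), heavy_atom_count(c2213$smiles) - 1)
  expect_error(apply_variant(va, lib$variants[[1]]), "not found")
})

test_that("invalid fragments are rejected with the entry named", {
  sc <- lib_fixture()$scaffold
  bad <- list(group_library("R2", tibble::tibble(
    label = "R2bad", smiles = "Qq", description = "broken")))
  expect_error(enumerate_one_region(sc, bad), "R2bad")
})
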