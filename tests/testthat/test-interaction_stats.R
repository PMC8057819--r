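test_that("replicate pair formation matches the design size", {
  tabs <- full_design_tables(c(0.61, 0.62, 0.63, 0.64), 0.2, 0.5)
  cfg <- permutation_config(seed = 3)
  pairs <- form_prediction_pairs(tabs$abundance, tabs$biomass,
                                 c("cs1", "cs2"), "TaxA", config = cfg)
  expect_equal(nrow(pairs), 8)
  expect_equal(as.vector(table(pairs$inoculum)), c(4L, 4L))
  # single-inoculum mode yields 4 pairs
  one <- full_design_tables(0.6, 0.2, 0.5, inocula = "I1")
  pairs1 <- form_prediction_pairs(one$abundance, one$biomass,
                                  c("cs1", "cs2"), "TaxA", config = cfg)
  expect_equal(nrow(pairs1), 4)
  # each observed mixture replicate used at most once per inoculum
  tabs2 <- full_design_tables(0.6, 0.2, c(0.51, 0.52, 0.53, 0.54))
  p2 <- form_prediction_pairs(tabs2$abundance, tabs2$biomass,
                              c("cs1", "cs2"), "TaxA", config = cfg)
  for (ino in c("I1", "I2"))
    expect_false(anyDuplicated(p2$observed[p2$inoculum == ino]) > 0)
})

test_that("without-replacement matching is bounded by replicate counts", {
  tabs <- full_design_tables(0.6, 0.2, 0.5)
  drop_one <- !(tabs$abundance$environment == "cs1+cs2" &
                tabs$abundance$inoculum == "I1" &
                tabs$abundance$replicate == 4)
  pairs <- form_prediction_pairs(tabs$abundance[drop_one, ], tabs$biomass,
                                 c("cs1", "cs2"), "TaxA",
                                 config = permutation_config(seed = 1))
  expect_equal(nrow(pairs), 7)  # 3 + 4
  # fewer than 2 replicates in a treatment is an error
  lone <- tabs$abundance[!(tabs$abundance$environment == "cs1" &
                           tabs$abundance$replicate > 1), ]
  expect_error(
    form_prediction_pairs(lone, tabs$biomass, c("cs1", "cs2"), "TaxA"),
    "insufficient replication")
})

test_that("permutation test calls clear offsets and not exact nulls", {
  cfg <- permutation_config(seed = 11)
  # observed equals predicted exactly: zero-variance differences, never
  # significant
  tabs <- full_design_tables(0.6, 0.2, 0.4)
  res <- suppressWarnings(
    permutation_interaction_test(tabs$abundance, tabs$biomass,
                                 c("cs1", "cs2"), "TaxA", "positive", cfg))
  expect_false(res$significant)
  expect_equal(res$frac_significant, 0)
  expect_equal(res$n_pairs, 8)
  # constant offset +0.3 with small replicate noise: every permutation
  # significant in the positive direction, none in the negative
  set.seed(42)
  noisy <- function(x) x + rnorm(8, 0, 0.01)
  tabs <- full_design_tables(noisy(0.5), noisy(0.1), noisy(0.6))
  pos <- permutation_interaction_test(tabs$abundance, tabs$biomass,
                                      c("cs1", "cs2"), "TaxA", "positive",
                                      cfg)
  neg <- permutation_interaction_test(tabs$abundance, tabs$biomass,
                                      c("cs1", "cs2"), "TaxA", "negative",
                                      cfg)
  expect_true(pos$significant)
  expect_equal(pos$frac_significant, 1.0)
  expect_false(neg$significant)
  # offsets alternating +/-0.3 (mean 0): no direction wins
  tabs <- full_design_tables(0.5, 0.1, 0.3 + c(0.3, -0.3))
  for (dir in c("positive", "negative")) {
    res <- permutation_interaction_test(tabs$abundance, tabs$biomass,
                                        c("cs1", "cs2"), "TaxA", dir, cfg)
    expect_false(res$significant)
    expect_lt(res$frac_significant, cfg$frac_threshold)
  }
})

test_that("interaction classification separates the three types", {
  expect_equal(classify_interaction(0.6, 0.1, 0.55, FALSE, FALSE), "none")
  set.seed(8)
  f1 <- 0.6 + rnorm(8, 0, 0.01)
  f2 <- 0.1 + rnorm(8, 0, 0.01)
  # between the singles: dominance
  expect_equal(
    classify_interaction(f1, f2, 0.55 + rnorm(8, 0, 0.01), TRUE, FALSE),
    "dominance")
  # above the larger single with tight replicates: synergy
  expect_equal(
    classify_interaction(0.3 + rnorm(8, 0, 0.01), 0.4 + rnorm(8, 0, 0.01),
                         0.8 + rnorm(8, 0, 0.01), TRUE, FALSE),
    "synergy")
  # below the smaller single: antagonism
  expect_equal(
    classify_interaction(f1, f2, 0.02 + rnorm(8, 0, 0.005), FALSE, TRUE),
    "antagonism")
  # single-replicate groups: point comparison with a warning
  expect_warning(
    type <- classify_interaction(0.3, 0.4, 0.8, TRUE, FALSE),
    "low confidence")
  expect_equal(type, "synergy")
})

test_that("the dominant nutrient follows the epsilon sign rule", {
  expect_equal(dominant_nutrient(0.6, 0.1, +1, "glucose", "succinate"),
               "glucose")
  expect_equal(dominant_nutrient(0.6, 0.1, -1, "glucose", "succinate"),
               "succinate")
  expect_true(is.na(dominant_nutrient(0.4, 0.4, +1)))
})

test_that("dominance index sign conventions hold for all pair classes", {
  classes <- c(glucose = "sugar", succinate = "acid", fructose = "sugar")
  expect_equal(dominance_index(0.3, "glucose", "SA", classes,
                               interaction_type = "none"), 0)
  expect_equal(dominance_index(0, "glucose", "SA", classes), 0)
  # sugar dominates: -|epsilon| regardless of epsilon sign
  expect_equal(dominance_index(0.22, "glucose", "SA", classes), -0.22)
  expect_equal(dominance_index(-0.22, "glucose", "SA", classes), -0.22)
  expect_equal(dominance_index(-0.22, "succinate", "SA", classes), 0.22)
  # same-class pairs are signed by the focal carbon source
  expect_equal(dominance_index(0.1, "glucose", "SS", focal_cs = "glucose"),
               -0.1)
  expect_equal(dominance_index(0.1, "fructose", "SS", focal_cs = "glucose"),
               0.1)
  # inocula disagreeing on the dominant nutrient: dual +/- report
  expect_equal(dominance_index(0.22, c("glucose", "succinate"), "SA",
                               classes), c(-0.22, 0.22))
  expect_equal(dominance_index(0.22, NA, "SA", classes), c(-0.22, 0.22))
  expect_error(dominance_index(0.1, "glucose", "XX", classes),
               "unknown pair class")
  expect_error(dominance_index(0.1, "glucose", "SS"), "focal_cs")
})

test_that("prevalence fractions count calls correctly", {
  calls <- data.frame(interaction_type = c("none", "none", "dominance",
                                           "dominance", "dominance",
                                           "synergy"))
  prev <- interaction_prevalence(calls)
  expect_equal(prev$frac_none, 1 / 3)
  expect_equal(prev$frac_dominance, 0.75)
  expect_equal(prev$frac_synergy, 0.25)
  expect_equal(prev$frac_antagonism, 0)
  all_none <- data.frame(interaction_type = rep("none", 10))
  prev <- interaction_prevalence(all_none)
  expect_equal(prev$frac_none, 1)
  expect_true(is.na(prev$frac_dominance))
  expect_error(interaction_prevalence(data.frame(interaction_type =
                                                   character(0))),
               "no interaction calls")
})

test_that("identical seed and config give identical calls", {
  d <- synth_design(true_epsilon = list("glucose+succinate" =
    c(Enterobacteriaceae = 0.15, Pseudomonadaceae = -0.15)))
  dat <- generate_abundance_dataset(d, seed = 21)
  run <- function() test_interactions(dat$abundance, dat$biomass,
                                      d$cs_classes, focal_cs = d$focal_cs,
                                      config = permutation_config(
                                        n_permutations = 200, seed = 5))
  expect_identical(run(), run())
})

test_that("genus-level mode keeps the inocula separate", {
  tabs <- full_design_tables(0.6, 0.1, 0.55)
  tabs$abundance$taxon_level <- "genus"
  calls <- suppressWarnings(
    test_interactions(tabs$abundance, tabs$biomass, two_class_map,
                      level = "genus", per_inoculum = TRUE,
                      config = permutation_config(n_permutations = 100,
                                                  seed = 2)))
  expect_setequal(unique(calls$inoculum), c("I1", "I2"))
  expect_equal(nrow(calls), 4)  # 2 inocula x 2 taxa
})
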