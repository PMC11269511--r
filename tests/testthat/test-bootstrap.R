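test_that("a cohort of identical individuals has zero bootstrap SE", {
  recs <- lapply(1:12, function(i)
    rec(paste0("i", i), hatch_age = 1, larva_end_age = 2, nymph_end_age = 4,
        sex = "female", death_age = 14))
  ch <- cohort(recs)
  est <- bootstrap_estimate(ch, "mean_female_longevity", B = 200, seed = 3)
  expect_identical(est$se, 0)
  expect_identical(est$point, 10)
  expect_equal(unname(est$ci95), c(10, 10))
})

test_that("bootstrap estimates are reproducible given the seed", {
  ch <- simulate_cohort(preset_config("control-like"), seed = 2)
  e1 <- bootstrap_estimate(ch, "mean_female_longevity", B = 300, seed = 7)
  e2 <- bootstrap_estimate(ch, "mean_female_longevity", B = 300, seed = 7)
  expect_identical(e1, e2)
  e3 <- bootstrap_estimate(ch, "mean_female_longevity", B = 300, seed = 8)
  expect_false(identical(e1$se, e3$se))
})

test_that("bootstrap SE of a mean tracks the classical s/sqrt(n)", {
  ratios <- vapply(1:20, function(seed) {
    ch <- simulate_cohort(preset_config("control-like", n = 60), seed = seed)
    lon <- unlist(lapply(ch$records, function(r) {
      if (r$sex == "female" && !is.na(r$nymph_end_age) && !is.na(r$death_age))
        r$death_age - r$nymph_end_age else NULL
    }))
    classical <- sd(lon) / sqrt(length(lon))
    est <- bootstrap_estimate(ch, "mean_female_longevity", B = 1000, seed = seed)
    est$se / classical
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("replicates resample whole individuals", {
  ch <- simulate_cohort(preset_config("control-like", n = 25), seed = 13)
  originals <- lapply(ch$records, function(r) r$individual_id)
  seen_foreign <- FALSE
  witness <- function(replicate) {
    ids <- lapply(replicate$records, function(r) r$individual_id)
    if (!all(unlist(ids) %in% unlist(originals))) seen_foreign <<- TRUE
    # every resampled record must be byte-identical to an original record
    ok <- all(vapply(replicate$records, function(r)
      any(vapply(ch$records, identical, logical(1), r)), logical(1)))
    if (!ok) seen_foreign <<- TRUE
    length(replicate$records)
  }
  est <- bootstrap_estimate(ch, witness, B = 100, seed = 1)
  expect_false(seen_foreign)
  expect_identical(est$point, 25L)
})

test_that("undefined statistics are counted and over-failure is an error", {
  # no males at all: mean_male_longevity fails on every replicate
  recs <- lapply(1:10, function(i)
    rec(paste0("f", i), hatch_age = 1, larva_end_age = 2, nymph_end_age = 3,
        sex = "female", death_age = 9))
  ch <- cohort(recs)
  expect_error(bootstrap_estimate(ch, "mean_male_longevity", B = 100, seed = 1),
               "degenerate")
  expect_error(bootstrap_estimate(ch, "mean_female_longevity", B = 50, seed = 1),
               "at least 100")
  expect_error(bootstrap_estimate(ch, "not_a_stat", B = 100, seed = 1),
               "unknown statistic")
})

test_that("paired test on a cohort against its copy covers zero", {
  ch <- simulate_cohort(preset_config("control-like"), seed = 5)
  tst <- paired_bootstrap_test(ch, ch, "mean_female_longevity", B = 400, seed = 2)
  expect_lte(tst$diff_ci95[1], 0)
  expect_gte(tst$diff_ci95[2], 0)
  expect_identical(tst$diff_point, 0)
  expect_gt(tst$p_value, 0.05)
})

test_that("the paired test separates presets with very different R0", {
  a <- simulate_cohort(preset_config("control-like", n = 200), seed = 6)
  b <- simulate_cohort(preset_config("stressor-like", n = 200), seed = 7)
  tst <- paired_bootstrap_test(a, b, "R0", B = 2000, seed = 3)
  expect_lt(tst$p_value, 0.05)
  expect_gt(tst$diff_ci95[1], 0)
  # percentile duality: 0 outside the CI iff p < 0.05
  expect_true((tst$diff_ci95[1] > 0 || tst$diff_ci95[2] < 0) == (tst$p_value < 0.05))
})

test_that("degenerate single-individual cohorts cannot be tested", {
  dead <- cohort(list(rec("x", death_age = 2)))
  expect_error(paired_bootstrap_test(dead, dead, "r", B = 100, seed = 1),
               "degenerate")
})
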