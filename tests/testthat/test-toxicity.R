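test_that("Henderson-Tilton correction reproduces known survivor-count cases", {
  expect_equal(corrected_mortality(50, 47, 50, 4), 91.49, tolerance = 0.005)
  expect_equal(corrected_mortality(50, 47, 50, 7), 85.11, tolerance = 0.005)
  expect_equal(corrected_mortality(50, 47, 50, 8), 82.98, tolerance = 0.005)
  # treated arm matching the control ratio shows no excess mortality
  expect_identical(corrected_mortality(50, 40, 30, 24), 0)
  # total kill
  expect_identical(corrected_mortality(50, 47, 50, 0), 100)
  # a treated arm outliving the control clamps to 0, not negative
  expect_identical(corrected_mortality(50, 40, 50, 45), 0)
  expect_error(corrected_mortality(50, 0, 50, 10), "no survivors")
  expect_error(corrected_mortality(50, 51, 50, 10), "cannot exceed")
})

test_that("Abbott form matches Henderson-Tilton with equal before-counts", {
  for (mt in c(0, 20, 64, 100)) {
    expect_equal(abbott_mortality(mt, 6),
                 corrected_mortality(100, 94, 100, 100 - mt),
                 tolerance = 1e-9)
  }
  expect_error(abbott_mortality(50, 100), "no survivors")
})

test_that("the reduction coefficient combines mortality and sublethal ratios", {
  expect_equal(reduction_coefficient(70, 3.5, 27.6, 84.4, 98.5)$ex,
               96.74, tolerance = 0.005)
  expect_equal(reduction_coefficient(68, 8.3, 27.6, 93.8, 98.5)$ex,
               90.84, tolerance = 0.005)
  # no effect at all
  expect_identical(reduction_coefficient(0, 10, 10, 90, 90)$ex, 0)
  # total kill is absorbing whatever the ratios
  expect_identical(reduction_coefficient(100, 20, 10, 99, 50)$ex, 100)
  # Ex = Mc when every ratio is exactly 1
  for (mc in c(0, 12.5, 70, 99.9)) {
    expect_equal(reduction_coefficient(mc, 7, 7, 88, 88,
                                       longevity_t = 9, longevity_c = 9,
                                       include_longevity = TRUE)$ex, mc)
  }
  # ratios above 1 can push the raw value negative; ex is clamped
  rc <- reduction_coefficient(0, 12, 10, 95, 90)
  expect_lt(rc$ex_raw, 0)
  expect_identical(rc$ex, 0)
  expect_error(reduction_coefficient(10, 5, 0, 90, 90), "positive")
  expect_error(reduction_coefficient(10, 5, 10, 90, 90, include_longevity = TRUE),
               "longevities")
})

test_that("Ex is monotone in Mc and antitone in each ratio", {
  base <- reduction_coefficient(50, 10, 20, 80, 90,
                                longevity_t = 8, longevity_c = 16,
                                include_longevity = TRUE)$ex
  expect_gt(reduction_coefficient(60, 10, 20, 80, 90, 8, 16, TRUE)$ex, base)
  expect_lt(reduction_coefficient(50, 12, 20, 80, 90, 8, 16, TRUE)$ex, base)
  expect_lt(reduction_coefficient(50, 10, 20, 85, 90, 8, 16, TRUE)$ex, base)
  expect_lt(reduction_coefficient(50, 10, 20, 80, 90, 10, 16, TRUE)$ex, base)
})

test_that("every published laboratory (Ex, class) pair re-classifies correctly", {
  # adult topical exposure assessments
  adult <- data.frame(
    ex = c(96.74, 75.91, 100, 100, 100, 100, 90.84, 98.6, 90.1, 78.75),
    class = c("III", "II", "IV", "IV", "IV", "IV", "III", "III", "III", "II")
  )
  # egg topical exposure assessments
  egg <- data.frame(
    ex = c(86.82, 83.82, 100, 100, 100, 100, 94.95, 87.85, 91.4, 83.6),
    class = c("III", "III", "IV", "IV", "IV", "IV", "III", "III", "III", "III")
  )
  both <- rbind(adult, egg)
  expect_identical(as.character(classify_iobc(both$ex, "lab")), both$class)
  # band edges under the documented half-open resolution
  expect_identical(as.character(classify_iobc(c(0, 29.99, 30, 79.9, 80, 99, 99.01, 100), "lab")),
                   c("I", "I", "II", "II", "III", "III", "IV", "IV"))
})

test_that("extended-laboratory classes follow the residue scheme", {
  resid <- data.frame(
    ex = c(72.45, 24.2, 17.89, 70.99, 57.9, 44.5, 16.4, 74.4, 14.3, 39.0,
           7.4, 99.8, 99.2, 98.7, 98.5, 16.5, 95.3, 94.8, 94.4, 92.6),
    class = c("III", "I", "I", "III", "III", "II", "I", "III", "I", "II",
              "I", "IV", "IV", "IV", "IV", "I", "IV", "IV", "IV", "IV")
  )
  expect_identical(as.character(classify_iobc(resid$ex, "extended_lab")),
                   resid$class)
  expect_identical(as.character(classify_iobc(c(24.99, 25, 50, 50.01, 75, 75.01), "extended_lab")),
                   c("I", "II", "II", "III", "III", "IV"))
})

test_that("persistence classification follows the recovery day", {
  mk <- function(days, classes) data.frame(days_after_application = days,
                                           iobc_class = classes)
  a <- assess_persistence(mk(4, "I"))
  expect_identical(as.character(a$persistence_class), "A")
  expect_identical(a$days_to_harmless, 4L)

  b <- assess_persistence(mk(c(4, 10), c("III", "I")))
  expect_identical(as.character(b$persistence_class), "B")
  expect_identical(b$days_to_harmless, 10L)

  cc <- assess_persistence(mk(c(4, 10, 20), c("III", "III", "I")))
  expect_identical(as.character(cc$persistence_class), "C")
  expect_identical(cc$days_to_harmless, 20L)

  d <- assess_persistence(mk(c(4, 10, 20, 31), c("IV", "IV", "IV", "IV")))
  expect_identical(as.character(d$persistence_class), "D")
  expect_true(is.na(d$days_to_harmless))

  # recovery observed only after day 30 is still class D
  late <- assess_persistence(mk(c(4, 31), c("IV", "I")))
  expect_identical(as.character(late$persistence_class), "D")

  expect_warning(
    nm <- assess_persistence(mk(c(4, 10, 20), c("I", "III", "I"))),
    "non-monotone")
  expect_identical(nm$days_to_harmless, 20L)
  expect_true(nm$nonmonotone)
})

test_that("residue series scoring corrects against the same-day control", {
  assays <- data.frame(
    treatment = c("control", "control", "pest", "pest"),
    days_after_application = c(4L, 10L, 4L, 10L),
    mortality_pct = c(6, 4, 53, 20),
    is_corrected = FALSE,
    fecundity_per_female = c(38, 39, 10, 30),
    viability_pct = c(100, 100, 80, 95)
  )
  ser <- assess_residue_series(assays, control = "control")
  expect_named(ser, "pest")
  s <- ser$pest
  expect_equal(s$mc[1], abbott_mortality(53, 6))
  expect_equal(s$ex[1], 100 - (100 - abbott_mortality(53, 6)) * (10 / 38) * (80 / 100),
               tolerance = 1e-9)
  expect_identical(s$iobc_class, as.character(classify_iobc(s$ex, "extended_lab")))
  expect_error(assess_residue_series(assays, control = "nope"), "not found")
})

test_that("cohort pairs score into the expected IOBC classes", {
  control <- simulate_cohort(preset_config("control-like", n = 120), seed = 41)
  # self-comparison: no effect
  self <- score_cohort_pair(control, control, "egg")
  expect_identical(self$ex, 0)
  expect_identical(as.character(self$iobc_class), "I")

  # total kill
  dead <- simulate_cohort(cohort_config(n = 120, p_hatch = 0,
                                        treatment = "lethal"), seed = 42)
  kill <- score_cohort_pair(control, dead, "egg")
  expect_identical(kill$ex, 100)
  expect_identical(as.character(kill$iobc_class), "IV")

  # a strong stressor scores far above the harmless band
  stressed <- simulate_cohort(preset_config("stressor-like", n = 120), seed = 43)
  hit <- score_cohort_pair(control, stressed, "egg")
  expect_gt(hit$ex, 70)
  expect_false(is.na(hit$R3))

  # adult variant omits the longevity ratio
  ad_c <- cohort(lapply(1:10, function(i)
    cohort_record(paste0("c", i), "ctrl", "topical_adult", nymph_end_age = 0,
                  sex = if (i <= 5) "female" else "male",
                  death_age = 12, daily_eggs = if (i <= 5) c("3" = 2L),
                  viability_trials = if (i <= 5) data.frame(eggs_tested = 2L, eggs_hatched = 2L))))
  ad_t <- cohort(lapply(1:10, function(i)
    cohort_record(paste0("t", i), "trt", "topical_adult", nymph_end_age = 0,
                  sex = if (i <= 5) "female" else "male",
                  death_age = if (i %% 2) 1L else 8L,
                  daily_eggs = if (i == 2) c("3" = 1L),
                  viability_trials = if (i == 2) data.frame(eggs_tested = 1L, eggs_hatched = 1L))))
  ad <- score_cohort_pair(ad_c, ad_t, "adult")
  expect_true(is.na(ad$R3))
  expect_equal(ad$mc, 50)   # 5 of 10 dead within 24 h, control all alive
})
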