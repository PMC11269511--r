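test_that("lx and mx are direct counts over the cohort", {
  # one dies at age 1, one lives through age 3
  ch <- cohort(list(rec("a", death_age = 1),
                    rec("b", death_age = 4)))
  sch <- build_life_schedule(ch)
  expect_equal(sch$lx, c(1, 0.5, 0.5, 0.5))

  # single adult female laying 2 eggs at age 1, alive ages 0-1
  ch <- cohort(list(cohort_record("f", "t", exposure_route = "topical_adult",
                                  nymph_end_age = 0, sex = "female",
                                  death_age = 2, daily_eggs = c("1" = 2L))))
  sch <- build_life_schedule(ch)
  expect_equal(sch$mx, c(0, 2))
  expect_equal(net_reproductive_rate(sch), 2)

  expect_error(build_life_schedule(cohort(list(), treatment = "t")), "empty")
})

test_that("schedule invariants hold on simulated cohorts", {
  for (preset in names(preset_configs())) {
    sch <- build_life_schedule(simulate_cohort(preset_config(preset, n = 80), seed = 5))
    expect_equal(sch$lx[1], 1)
    expect_true(all(diff(sch$lx) <= 1e-12))
    expect_true(all(sch$sxj >= 0))
    expect_true(all(abs(rowSums(sch$sxj) - sch$lx) < 1e-12))
    expect_true(all(sch$mx >= 0))
    expect_identical(sch$censored_count, 0L)
  }
})

test_that("net reproductive rate sums lx * mx", {
  expect_equal(net_reproductive_rate(fake_schedule(1, 2)), 2)
  expect_equal(net_reproductive_rate(fake_schedule(c(1, 0.5), c(0, 0))), 0)
  expect_equal(net_reproductive_rate(fake_schedule(c(1, 0.5, 0.25), c(0, 2, 4))), 2)
})

test_that("Euler-Lotka closed forms are recovered", {
  # all reproduction at age 0 with l0*m0 = 2: exp(-r)*2 = 1 -> r = ln 2
  expect_equal(solve_euler_lotka(fake_schedule(1, 2)), log(2), tolerance = 1e-9)
  # replacement rate R0 = 1 -> r = 0
  expect_equal(solve_euler_lotka(fake_schedule(1, 1)), 0, tolerance = 1e-9)
  # declining cohort: R0 = 0.5 at age 0 -> r = ln(0.5) < 0
  expect_equal(solve_euler_lotka(fake_schedule(1, 0.5)), log(0.5), tolerance = 1e-9)
  expect_error(solve_euler_lotka(fake_schedule(c(1, 0.5), c(0, 0))), "R0 = 0")
})

test_that("solver agrees with the grid-scan oracle on random schedules", {
  set.seed(1234)
  for (i in 1:20) {
    sch <- random_schedule()
    expect_equal(solve_euler_lotka(sch), grid_scan_r(sch), tolerance = 1e-6)
  }
})

test_that("r increases with fecundity and shares the sign of R0 - 1", {
  set.seed(99)
  for (i in 1:25) {
    sch <- random_schedule()
    r1 <- solve_euler_lotka(sch)
    R0 <- net_reproductive_rate(sch)
    if (abs(R0 - 1) > 1e-8) expect_identical(sign(r1), sign(R0 - 1))
    boosted <- fake_schedule(sch$lx, sch$mx * 1.5)
    expect_gt(solve_euler_lotka(boosted), r1)
  }
})

test_that("reproduction concentrated at one age gives T = x* + 1", {
  lx <- c(1, 0.8, 0.6, 0.5)
  mx <- c(0, 0, 0, 6)                   # only age x* = 3 reproduces
  sch <- fake_schedule(lx, mx)
  p <- demographic_parameters(sch)
  R0 <- 0.5 * 6
  expect_equal(p$R0, R0)
  expect_equal(p$r, log(R0) / 4, tolerance = 1e-9)
  expect_equal(p$T, 4, tolerance = 1e-9)
})

test_that("demographic parameters satisfy their identities", {
  sch <- fake_schedule(c(1, 0.9, 0.7), c(0, 1.5, 2))
  p <- demographic_parameters(sch)
  expect_identical(p$lambda, exp(p$r))
  expect_equal(p$T, log(p$R0) / p$r)

  # single-age textbook case
  p2 <- demographic_parameters(fake_schedule(1, 2))
  expect_equal(p2$R0, 2)
  expect_equal(p2$r, log(2), tolerance = 1e-9)
  expect_equal(p2$lambda, 2, tolerance = 1e-9)
  expect_equal(p2$T, 1, tolerance = 1e-9)

  # replacement-rate limit uses the weighted-age formula
  p3 <- demographic_parameters(fake_schedule(c(1, 0.5), c(0, 2)))
  expect_equal(p3$R0, 1)
  expect_equal(p3$r, 0, tolerance = 1e-8)
  expect_equal(p3$T, 2, tolerance = 1e-6)   # all reproduction at age 1 -> T = 2
})

test_that("survivorship summary scans the lx thresholds", {
  s <- survivorship_summary(fake_schedule(c(1, 0.6, 0.4, 0.1, 0), rep(0, 5)))
  expect_identical(s$median_survival_age, 2L)
  expect_identical(s$max_lifespan, 3L)

  s2 <- survivorship_summary(fake_schedule(c(1, 0.9), c(0, 0)))
  expect_true(is.na(s2$median_survival_age))

  sch <- build_life_schedule(simulate_cohort(preset_config("control-like", n = 500), seed = 8))
  med <- survivorship_summary(sch)$median_survival_age
  expect_gte(med, 15)
  expect_lte(med, 23)
})

test_that("cohort_summary reports the generator's stage structure", {
  ch <- simulate_cohort(preset_config("control-like", n = 400), seed = 17)
  s <- cohort_summary(ch)
  expect_equal(s$hatch_pct, 100)
  expect_equal(s$egg_duration, true_dur_mean(1.64, 34), tolerance = 0.08)
  expect_equal(s$preadult_duration,
               true_dur_mean(1.64, 34) + true_dur_mean(0.58, 8, 0L) +
                 true_dur_mean(2.27, 11),
               tolerance = 0.1)
  expect_gt(s$fecundity_per_female, 20)
  expect_lt(abs(s$viability_pct - 97), 2)
})
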