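# Age-stage two-sex life table: schedules and demographic parameters.
#
# All individuals of the cohort — male, female, and those dying immature —
# enter the denominators, following the two-sex framework: lx is the
# probability a newborn (of either sex) is alive at age x, and mx is the
# mean number of eggs laid at age x per individual alive at that age.

LIFE_STAGES <- c("egg", "larva", "nymph", "female", "male")

#' Build the age-stage life schedule of a cohort
#'
#' Tabulates, for each age x from 0 to the last age any individual was
#' alive, the age-stage survival matrix `sxj` (probability a newborn is
#' alive and in stage j at age x, denominator = initial cohort size), the
#' survivorship curve `lx = rowSums(sxj)`, and the age-specific fecundity
#' `mx` (eggs laid at age x divided by individuals alive at age x,
#' two-sex denominator). Individuals alive at the last census
#' (right-censored) contribute up to their last observed age and are
#' excluded thereafter; their count is reported in `censored_count`.
#'
#' @param x a validated [cohort()] with at least one record.
#' @return An object of class `life_schedule` with elements `ages`, `sxj`,
#'   `lx`, `mx`, `n_initial`, and `censored_count`.
#' @export
build_life_schedule <- function(x) {
  stopifnot(inherits(x, "cohort"))
  if (x$n_initial == 0L) stop("cannot build a life schedule from an empty cohort")
  last_alive <- vapply(x$records, last_alive_age, integer(1))
  censored <- vapply(x$records, function(r) is.na(r$death_age), logical(1))
  if (all(censored & last_alive == 0L)) {
    stop("all individuals censored at age 0; no survival information")
  }
  amax <- max(last_alive)
  ages <- 0:amax
  sxj <- matrix(0, nrow = amax + 1L, ncol = length(LIFE_STAGES),
                dimnames = list(age = ages, stage = LIFE_STAGES))
  eggs_at_age <- numeric(amax + 1L)
  for (k in seq_along(x$records)) {
    r <- x$records[[k]]
    if (last_alive[k] < 0L) next         # dead at age 0: never counted alive
    for (a in 0:last_alive[k]) {
      st <- stage_at_age(r, a)
      sxj[a + 1L, st] <- sxj[a + 1L, st] + 1
    }
    if (length(r$daily_eggs)) {
      idx <- as.integer(names(r$daily_eggs)) + 1L
      eggs_at_age[idx] <- eggs_at_age[idx] + r$daily_eggs
    }
  }
  alive <- unname(rowSums(sxj))
  sxj <- sxj / x$n_initial
  lx <- alive / x$n_initial
  mx <- unname(ifelse(alive > 0, eggs_at_age / alive, 0))
  structure(list(ages = ages, sxj = sxj, lx = lx, mx = mx,
                 n_initial = x$n_initial,
                 censored_count = sum(censored)),
            class = "life_schedule")
}

#' @export
print.life_schedule <- function(x, ...) {
  cat(sprintf("<life_schedule> ages 0..%d, n_initial = %d, censored = %d\n",
              max(x$ages), x$n_initial, x$censored_count))
  cat(sprintf("  l0 = %.3f, final lx = %.3f, total lx*mx = %.3f\n",
              x$lx[1], x$lx[length(x$lx)], sum(x$lx * x$mx)))
  invisible(x)
}

#' Convert a life schedule to a data frame
#'
#' @param x a `life_schedule`.
#' @param ... unused.
#' @return Data frame with age, lx, mx, and one column per stage of `sxj`.
#' @export
as.data.frame.life_schedule <- function(x, ...) {
  cbind(data.frame(age = x$ages, lx = x$lx, mx = x$mx),
        as.data.frame(unclass(x$sxj)))
}

#' Net reproductive rate
#'
#' `R0 = sum(lx * mx)`: the expected lifetime egg production per newborn
#' individual (two-sex convention).
#'
#' @param schedule a [build_life_schedule()] result.
#' @return Non-negative scalar.
#' @export
net_reproductive_rate <- function(schedule) {
  stopifnot(inherits(schedule, "life_schedule"))
  sum(schedule$lx * schedule$mx)
}

#' Intrinsic rate of increase from the Euler-Lotka renewal equation
#'
#' Solves `sum_x exp(-r * (x + 1)) * lx * mx = 1` for `r`, with ages
#' indexed from 0. Note the `(x + 1)` exponent: this is the age-indexing
#' convention of the age-stage two-sex framework (ages counted from 0,
#' reproduction credited at the end of the day), not the classic
#' `exp(-r * x)` form. Negative `r` is a legitimate solution for declining
#' cohorts.
#'
#' The left side is strictly decreasing in `r`, so the root is unique; it
#' is found by geometric widening of the bracket `[-1, 2]` followed by
#' bisection with Newton refinement, to a residual below `tol`.
#'
#' @param schedule a [build_life_schedule()] result (or any list with
#'   `lx` and `mx`).
#' @param tol tolerance on the renewal-equation residual.
#' @param max_iter iteration cap for the refinement loop.
#' @return The intrinsic rate of increase `r` (per day).
#' @export
solve_euler_lotka <- function(schedule, tol = 1e-10, max_iter = 200L) {
  lxmx <- schedule$lx * schedule$mx
  if (sum(lxmx) <= 0) {
    stop("R0 = 0: the renewal equation has no solution for a sterile cohort")
  }
  xp1 <- seq_along(lxmx)                 # x + 1 for ages 0,1,...
  f <- function(r) sum(exp(-r * xp1) * lxmx) - 1
  fprime <- function(r) -sum(xp1 * exp(-r * xp1) * lxmx)

  lo <- -1; hi <- 2; width <- 3
  while (f(lo) < 0) { lo <- lo - width; width <- width * 2 }
  width <- 3
  while (f(hi) > 0) { hi <- hi + width; width <- width * 2 }

  r <- (lo + hi) / 2
  for (it in seq_len(max_iter)) {
    fr <- f(r)
    if (abs(fr) < tol) return(r)
    if (fr > 0) lo <- r else hi <- r
    r_newton <- r - fr / fprime(r)
    r <- if (is.finite(r_newton) && r_newton > lo && r_newton < hi) {
      r_newton
    } else {
      (lo + hi) / 2
    }
  }
  stop(sprintf(
    "Euler-Lotka iteration did not converge within %d steps (bracket [%g, %g], residual %g)",
    max_iter, lo, hi, f(r)))
}

#' Demographic parameters of a cohort schedule
#'
#' Bundles the net reproductive rate `R0`, the intrinsic rate of increase
#' `r` from [solve_euler_lotka()], the finite rate of increase
#' `lambda = exp(r)`, and the mean generation time `T = log(R0) / r` (the
#' time the population needs to grow `R0`-fold when increasing at rate
#' `r`). For `r` numerically at 0 (`R0 = 1`) the limit
#' `T = sum(x * lx * mx) / R0 + 1` is used, which is the continuous
#' extension of `log(R0) / r` under the `(x + 1)` exponent convention.
#'
#' @param schedule a [build_life_schedule()] result.
#' @return Object of class `demographic_params`: list with `R0`, `r`,
#'   `lambda`, and `T`.
#' @export
demographic_parameters <- function(schedule) {
  R0 <- net_reproductive_rate(schedule)
  if (R0 <= 0) stop("R0 = 0: demographic parameters are undefined for a sterile cohort")
  r <- solve_euler_lotka(schedule)
  lambda <- exp(r)
  Tgen <- if (abs(r) < 1e-9) {
    sum(schedule$ages * schedule$lx * schedule$mx) / R0 + 1
  } else {
    log(R0) / r
  }
  structure(list(R0 = R0, r = r, lambda = lambda, T = Tgen),
            class = "demographic_params")
}

#' @export
print.demographic_params <- function(x, ...) {
  cat(sprintf("R0 = %.3f offspring/individual, r = %.4f /day, lambda = %.4f /day, T = %.2f days\n",
              x$R0, x$r, x$lambda, x$T))
  invisible(x)
}

#' Survivorship summary: median survival age and maximum lifespan
#'
#' @param schedule a [build_life_schedule()] result.
#' @return List with `median_survival_age` (smallest age with `lx < 0.5`,
#'   `NA` if survivorship never drops below 50%) and `max_lifespan`
#'   (largest age with `lx > 0`).
#' @export
survivorship_summary <- function(schedule) {
  below <- which(schedule$lx < 0.5)
  alive <- which(schedule$lx > 0)
  list(
    median_survival_age = if (length(below)) schedule$ages[below[1]] else NA_integer_,
    max_lifespan = schedule$ages[alive[length(alive)]]
  )
}

#' Per-treatment cohort summary statistics
#'
#' The descriptive statistics reported for life-table response
#' experiments: stage-specific survival percentages, mean stage durations
#' (with standard errors), adult longevities by sex, lifetime fecundity per
#' female that reached adulthood, and pooled egg viability.
#'
#' @param x a [cohort()].
#' @return One-row data frame of summary statistics.
#' @export
cohort_summary <- function(x) {
  stopifnot(inherits(x, "cohort"))
  rs <- x$records
  get <- function(f) vapply(rs, f, numeric(1))
  hatch <- get(function(r) as.numeric(!is.na(r$hatch_age)))
  reached_nymph <- get(function(r) as.numeric(!is.na(r$larva_end_age)))
  reached_adult <- get(function(r) as.numeric(!is.na(r$nymph_end_age)))
  mse <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(NA_real_, NA_real_))
    c(mean(v), stats::sd(v) / sqrt(length(v)))
  }
  egg_dur <- mse(get(function(r) if (!is.na(r$hatch_age)) r$hatch_age else NA_real_))
  larva_dur <- mse(get(function(r)
    if (!is.na(r$larva_end_age)) r$larva_end_age - r$hatch_age else NA_real_))
  nymph_dur <- mse(get(function(r)
    if (!is.na(r$nymph_end_age)) r$nymph_end_age - r$larva_end_age else NA_real_))
  preadult <- mse(get(function(r)
    if (!is.na(r$nymph_end_age) && r$exposure_route != "topical_adult")
      r$nymph_end_age else NA_real_))
  longev <- function(want_sex) mse(get(function(r) {
    if (r$sex == want_sex && !is.na(r$nymph_end_age) && !is.na(r$death_age))
      r$death_age - r$nymph_end_age else NA_real_
  }))
  lf <- longev("female"); lm <- longev("male")
  fec <- mse(get(function(r) {
    if (r$sex == "female" && !is.na(r$nymph_end_age)) sum(r$daily_eggs) else NA_real_
  }))
  tested <- sum(get(function(r) sum(r$viability_trials$eggs_tested)))
  hatched <- sum(get(function(r) sum(r$viability_trials$eggs_hatched)))

  n_hatched <- sum(hatch)
  n_nymph <- sum(reached_nymph)
  n_adult <- sum(reached_adult)
  data.frame(
    treatment = x$treatment,
    n_initial = x$n_initial,
    hatch_pct = 100 * n_hatched / x$n_initial,
    larva_survival_pct = if (n_hatched > 0) 100 * n_nymph / n_hatched else NA_real_,
    nymph_survival_pct = if (n_nymph > 0) 100 * n_adult / n_nymph else NA_real_,
    preadult_survival_pct = 100 * n_adult / x$n_initial,
    egg_duration = egg_dur[1], egg_duration_se = egg_dur[2],
    larva_duration = larva_dur[1], larva_duration_se = larva_dur[2],
    nymph_duration = nymph_dur[1], nymph_duration_se = nymph_dur[2],
    preadult_duration = preadult[1], preadult_duration_se = preadult[2],
    female_longevity = lf[1], female_longevity_se = lf[2],
    male_longevity = lm[1], male_longevity_se = lm[2],
    fecundity_per_female = fec[1], fecundity_per_female_se = fec[2],
    viability_pct = if (tested > 0) 100 * hatched / tested else NA_real_,
    stringsAsFactors = FALSE
  )
}
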