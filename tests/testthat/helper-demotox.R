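# shared fixtures and independent oracles

# minimal record in treatment "t"
rec <- function(id, ...) cohort_record(id, "t", ...)

# a small well-formed cohort: one female that reproduced, one male,
# one immature death
tiny_cohort <- function() {
  cohort(list(
    rec("f1", hatch_age = 2, larva_end_age = 3, nymph_end_age = 5,
        sex = "female", death_age = 12,
        daily_eggs = c("7" = 2L, "8" = 1L),
        viability_trials = data.frame(eggs_tested = 3L, eggs_hatched = 3L)),
    rec("m1", hatch_age = 2, larva_end_age = 2, nymph_end_age = 4,
        sex = "male", death_age = 10),
    rec("d1", hatch_age = 2, death_age = 3)
  ))
}

# wrap bare lx/mx vectors as a life_schedule for the parameter functions
fake_schedule <- function(lx, mx) {
  structure(list(ages = seq_along(lx) - 1L, lx = lx, mx = mx,
                 n_initial = NA_integer_, censored_count = 0L),
            class = "life_schedule")
}

# random small schedule with positive reproduction
random_schedule <- function() {
  k <- sample(3:8, 1)
  lx <- cumprod(c(1, stats::runif(k - 1, 0.5, 1)))
  mx <- stats::runif(k, 0, 2) * stats::rbinom(k, 1, 0.7)
  if (sum(lx * mx) == 0) mx[k] <- 1
  fake_schedule(lx, mx)
}

# Independent grid-scan oracle for the Euler-Lotka root: brute-force scan
# of sum(exp(-r*(x+1)) * lx * mx) - 1 over successively finer grids of
# candidate r values, no Newton steps, no bisection reuse from the solver.
grid_scan_r <- function(schedule, final_step = 1e-7) {
  lxmx <- schedule$lx * schedule$mx
  xp1 <- seq_along(lxmx)
  f <- function(r) sum(exp(-r * xp1) * lxmx) - 1
  lo <- -1; hi <- 2
  while (f(lo) < 0) lo <- lo - 1
  while (f(hi) > 0) hi <- hi + 1
  step <- 1e-3
  repeat {
    grid <- seq(lo, hi, by = step)
    vals <- vapply(grid, f, numeric(1))
    i <- max(which(vals >= 0))          # f is decreasing in r
    lo <- grid[i]
    hi <- min(grid[i] + step, hi)
    if (step <= final_step) return((lo + hi) / 2)
    step <- step / 10
  }
}

# exact mean of the discretized-gamma duration model (generator truth)
true_dur_mean <- function(mean, shape, min_days = 1L) {
  demotox:::dur_mean(mean, shape, min_days)
}
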