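# Bootstrap standard errors and paired bootstrap tests for cohort-level
# statistics. The resampling unit is always the individual: each replicate
# draws n_initial whole life-history records with replacement.

#' Built-in cohort statistics
#'
#' Named statistics usable by [bootstrap_estimate()] and
#' [paired_bootstrap_test()]. Each maps a cohort to one number and returns
#' `NA` when undefined on a resample (e.g. `r` for a replicate with no
#' reproduction). Available names: `R0`, `r`, `lambda`, `T`,
#' `mean_female_longevity`, `mean_male_longevity`, `fecundity_per_female`,
#' `viability_pct`, `preadult_survival_pct`, `median_survival_age`.
#'
#' @return Named list of functions `cohort -> numeric(1)`.
#' @export
cohort_statistics <- function() {
  params_or_na <- function(ch, what) {
    sched <- tryCatch(build_life_schedule(ch), error = function(e) NULL)
    if (is.null(sched)) return(NA_real_)
    R0 <- net_reproductive_rate(sched)
    if (what == "R0") return(R0)
    if (R0 <= 0) return(NA_real_)
    p <- demographic_parameters(sched)
    p[[what]]
  }
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  rec_stat <- function(f) function(ch) {
    mean_or_na(unlist(lapply(ch$records, f)))
  }
  list(
    R0 = function(ch) params_or_na(ch, "R0"),
    r = function(ch) params_or_na(ch, "r"),
    lambda = function(ch) params_or_na(ch, "lambda"),
    T = function(ch) params_or_na(ch, "T"),
    mean_female_longevity = rec_stat(function(r) {
      if (r$sex == "female" && !is.na(r$nymph_end_age) && !is.na(r$death_age))
        r$death_age - r$nymph_end_age else NULL
    }),
    mean_male_longevity = rec_stat(function(r) {
      if (r$sex == "male" && !is.na(r$nymph_end_age) && !is.na(r$death_age))
        r$death_age - r$nymph_end_age else NULL
    }),
    fecundity_per_female = rec_stat(function(r) {
      if (r$sex == "female" && !is.na(r$nymph_end_age)) sum(r$daily_eggs) else NULL
    }),
    viability_pct = function(ch) {
      tested <- sum(vapply(ch$records, function(r) sum(r$viability_trials$eggs_tested), numeric(1)))
      hatched <- sum(vapply(ch$records, function(r) sum(r$viability_trials$eggs_hatched), numeric(1)))
      if (tested > 0) 100 * hatched / tested else NA_real_
    },
    preadult_survival_pct = function(ch) {
      100 * sum(vapply(ch$records, function(r) !is.na(r$nymph_end_age), logical(1))) / ch$n_initial
    },
    median_survival_age = function(ch) {
      s <- tryCatch(build_life_schedule(ch), error = function(e) NULL)
      if (is.null(s)) return(NA_real_)
      as.numeric(survivorship_summary(s)$median_survival_age)
    }
  )
}

resolve_statistic <- function(statistic) {
  if (is.function(statistic)) {
    return(list(name = "custom", fn = statistic))
  }
  stats_list <- cohort_statistics()
  if (!statistic %in% names(stats_list)) {
    stop("unknown statistic '", statistic, "'; available: ",
         paste(names(stats_list), collapse = ", "))
  }
  list(name = statistic, fn = stats_list[[statistic]])
}

# lightweight resample: reuse the validated records, skip re-validation
resample_cohort <- function(x, idx) {
  structure(list(treatment = x$treatment, n_initial = length(idx),
                 records = x$records[idx]), class = "cohort")
}

boot_replicates <- function(x, fn, B, seed) {
  set.seed(as.integer(seed))
  n <- x$n_initial
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  vapply(seq_len(B), function(b) {
    val <- tryCatch(fn(resample_cohort(x, idx[b, ])), error = function(e) NA_real_)
    if (length(val) != 1 || !is.finite(val)) NA_real_ else as.numeric(val)
  }, numeric(1))
}

#' Bootstrap standard error of a cohort statistic
#'
#' Resamples `n_initial` individuals with replacement `B` times,
#' recomputes the statistic on each replicate, and reports the bootstrap
#' standard error (SD of the replicates) and 95% percentile interval.
#' Replicates on which the statistic is undefined (for example `r` when a
#' resample contains no reproducing female) are dropped and counted in
#' `n_failed`; if more than half the replicates fail the estimate is
#' considered degenerate and an error is thrown.
#'
#' @param x a [cohort()].
#' @param statistic name of a built-in statistic (see
#'   [cohort_statistics()]) or a function `cohort -> numeric(1)`.
#' @param B number of bootstrap replicates (>= 100; published analyses of
#'   this kind use 100,000).
#' @param seed integer RNG seed; the result is fully reproducible given
#'   the seed.
#' @return Object of class `bootstrap_estimate`: list with
#'   `statistic_name`, `point` (statistic on the full cohort), `se`,
#'   `ci95`, `B`, `seed`, `n_failed`.
#' @export
bootstrap_estimate <- function(x, statistic, B = 100000L, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  if (B < 100) stop("B must be at least 100")
  st <- resolve_statistic(statistic)
  point <- st$fn(x)
  reps <- boot_replicates(x, st$fn, B, seed)
  ok <- reps[!is.na(reps)]
  n_failed <- B - length(ok)
  if (n_failed > B / 2) {
    stop("statistic '", st$name, "' undefined on ", n_failed, " of ", B,
         " replicates; estimate is degenerate")
  }
  structure(list(
    statistic_name = st$name,
    point = point,
    se = stats::sd(ok),
    ci95 = unname(stats::quantile(ok, c(0.025, 0.975), type = 7)),
    B = as.integer(B),
    seed = as.integer(seed),
    n_failed = as.integer(n_failed)
  ), class = "bootstrap_estimate")
}

#' @export
print.bootstrap_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4f (bootstrap SE %.4f, 95%% CI [%.4f, %.4f], B = %d, %d failed)\n",
              x$statistic_name, x$point, x$se, x$ci95[1], x$ci95[2],
              x$B, x$n_failed))
  invisible(x)
}

#' Paired bootstrap test for a difference between two cohorts
#'
#' Each replicate resamples both cohorts independently and records the
#' difference `statistic(a) - statistic(b)`. The two-sided p-value is
#' `2 * min(P(diff <= 0), P(diff >= 0))` over the successful replicates,
#' floored at `1 / B` (the resolution of the resampling), and the 95%
#' interval is the 2.5/97.5 percentile range of the differences.
#'
#' @param a,b two [cohort()]s supporting the statistic.
#' @inheritParams bootstrap_estimate
#' @return Object of class `paired_test_result`: list with
#'   `statistic_name`, `diff_point`, `diff_ci95`, `p_value`, `B`, `seed`,
#'   `n_failed`.
#' @export
paired_bootstrap_test <- function(a, b, statistic, B = 100000L, seed = 1L) {
  stopifnot(inherits(a, "cohort"), inherits(b, "cohort"))
  if (B < 100) stop("B must be at least 100")
  st <- resolve_statistic(statistic)
  reps_a <- boot_replicates(a, st$fn, B, seed)
  reps_b <- boot_replicates(b, st$fn, B, seed + 1L)
  diffs <- reps_a - reps_b
  ok <- diffs[!is.na(diffs)]
  n_failed <- B - length(ok)
  if (n_failed > B / 2) {
    stop("statistic '", st$name, "' undefined on ", n_failed, " of ", B,
         " paired replicates; test is degenerate")
  }
  p <- 2 * min(mean(ok <= 0), mean(ok >= 0))
  p <- min(1, max(p, 1 / B))
  structure(list(
    statistic_name = st$name,
    diff_point = st$fn(a) - st$fn(b),
    diff_ci95 = unname(stats::quantile(ok, c(0.025, 0.975), type = 7)),
    p_value = p,
    B = as.integer(B),
    seed = as.integer(seed),
    n_failed = as.integer(n_failed)
  ), class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("diff(%s) = %.4f, 95%% CI [%.4f, %.4f], p = %.4g (B = %d)\n",
              x$statistic_name, x$diff_point, x$diff_ci95[1], x$diff_ci95[2],
              x$p_value, x$B))
  invisible(x)
}
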