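# internal helpers shared across modules

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published toxicity tables use
#' conventional half-up rounding, so reports and classifications go through
#' this helper.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded with ties going away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Discretized gamma duration model: a gamma draw with the given mean and
# shape, rounded to the nearest whole day, with all mass below `min_days`
# lumped onto `min_days`. Daily-census data cannot resolve finer grain.

rdur <- function(n, mean, shape, min_days = 1L) {
  stopifnot(mean > 0, shape > 0)
  pmax(min_days, as.integer(round(stats::rgamma(n, shape = shape, rate = shape / mean))))
}

# P(D = d) for the discretized duration; vectorised over d
ddur <- function(d, mean, shape, min_days = 1L) {
  rate <- shape / mean
  hi <- stats::pgamma(d + 0.5, shape = shape, rate = rate)
  lo <- ifelse(d <= min_days, 0, stats::pgamma(d - 0.5, shape = shape, rate = rate))
  out <- hi - lo
  out[d < min_days] <- 0
  out
}

# support of the discretized duration covering all but ~1e-10 of the mass
dur_support <- function(mean, shape, min_days = 1L) {
  dmax <- max(min_days, ceiling(stats::qgamma(1 - 1e-10, shape = shape, rate = shape / mean)) + 1L)
  seq.int(min_days, dmax)
}

# full pmf vector indexed 0..dmax (zero below min_days); used by the
# analytic schedule convolutions
dur_pmf <- function(mean, shape, min_days = 1L) {
  sup <- dur_support(mean, shape, min_days)
  p <- ddur(sup, mean, shape, min_days)
  out <- numeric(max(sup) + 1L)
  out[sup + 1L] <- p
  out / sum(out)
}

dur_mean <- function(mean, shape, min_days = 1L) {
  sup <- dur_support(mean, shape, min_days)
  sum(sup * ddur(sup, mean, shape, min_days))
}

# convolution of two pmfs given as vectors indexed from age 0
conv_pmf <- function(p, q) {
  n <- length(p) + length(q) - 1L
  out <- numeric(n)
  for (i in seq_along(p)) {
    if (p[i] > 0) {
      idx <- i + seq_along(q) - 1L
      out[idx] <- out[idx] + p[i] * q
    }
  }
  out
}
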