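# Corrected mortality, the reduction coefficient Ex, and IOBC toxicity
# classification.
#
# Ex folds lethal and sublethal pesticide effects into one percentage:
#   Ex = 100 - (100 - Mc) * R1 * R2 (* R3)
# where Mc is control-corrected mortality, R1 the treated/control ratio of
# eggs laid per female, R2 the ratio of egg viability, and R3 (egg-stage
# assessments only) the ratio of adult female longevity. Two IOBC class
# schemes are supported: the laboratory scheme used for topical exposure
# and the extended-laboratory scheme used for aged-residue assays.

#' Henderson-Tilton corrected mortality
#'
#' `Mc = 100 * (1 - (Cb * Ta) / (Ca * Tb))` where `Cb`/`Ca` are live
#' control counts before/after and `Tb`/`Ta` live treated counts
#' before/after. With equal before-counts this reduces to the
#' Abbott/Schneider-Orelli correction on survival fractions. The result is
#' clamped to `[0, 100]` (a treatment arm outliving the control scores 0).
#'
#' @param control_before,control_after live individuals in the control arm
#'   before and after the assessment window.
#' @param treated_before,treated_after live individuals in the treated arm.
#' @return Corrected mortality in percent.
#' @examples
#' corrected_mortality(50, 47, 50, 4)   # 91.49
#' @export
corrected_mortality <- function(control_before, control_after,
                                treated_before, treated_after) {
  stopifnot(control_before > 0, treated_before > 0)
  if (control_after > control_before || treated_after > treated_before) {
    stop("live counts after treatment cannot exceed counts before")
  }
  if (control_after <= 0) {
    stop("corrected mortality is undefined when the control arm has no survivors")
  }
  mc <- 100 * (1 - (control_before * treated_after) /
                 (control_after * treated_before))
  clamp(mc, 0, 100)
}

#' Abbott-corrected mortality from percent mortalities
#'
#' Equal-initial-count form of the Henderson-Tilton correction, working on
#' percent mortality: `Mc = 100 * (1 - (100 - Mt) / (100 - Mctrl))`.
#' Used for residue assays where only percent mortality per arm is
#' recorded.
#'
#' @param treated_mortality_pct,control_mortality_pct percent mortality in
#'   the treated and control arms.
#' @return Corrected mortality in percent, clamped to `[0, 100]`.
#' @export
abbott_mortality <- function(treated_mortality_pct, control_mortality_pct) {
  stopifnot(treated_mortality_pct >= 0, treated_mortality_pct <= 100,
            control_mortality_pct >= 0, control_mortality_pct <= 100)
  if (control_mortality_pct >= 100) {
    stop("corrected mortality is undefined when the control arm has no survivors")
  }
  clamp(100 * (1 - (100 - treated_mortality_pct) /
                 (100 - control_mortality_pct)), 0, 100)
}

#' Reduction coefficient Ex
#'
#' Combines corrected mortality with treated/control ratios of fecundity
#' (`R1`), egg viability (`R2`), and — for egg-stage assessments — adult
#' female longevity (`R3`):
#' `Ex = 100 - (100 - Mc) * R1 * R2` (adult and residue variants) or
#' `Ex = 100 - (100 - Mc) * R1 * R2 * R3` (egg variant,
#' `include_longevity = TRUE`). Ratios are used exactly as computed and may
#' exceed 1 (a treated arm can out-perform the control on one trait); the
#' returned `ex` is clamped to `[0, 100]` for classification while
#' `ex_raw` preserves the unclamped value.
#'
#' @param mc corrected mortality in percent.
#' @param fecundity_t,fecundity_c eggs per female, treated and control.
#' @param viability_t,viability_c percent of eggs hatching.
#' @param longevity_t,longevity_c adult female longevity in days; required
#'   only when `include_longevity = TRUE`.
#' @param include_longevity logical; include the longevity ratio `R3`
#'   (egg-stage assessments).
#' @return List with `ex` (clamped), `ex_raw`, `mc`, and the ratios `R1`,
#'   `R2`, `R3` (`NA` when not used).
#' @examples
#' reduction_coefficient(70, 3.5, 27.6, 84.4, 98.5)$ex   # 96.74
#' @export
reduction_coefficient <- function(mc, fecundity_t, fecundity_c,
                                  viability_t, viability_c,
                                  longevity_t = NULL, longevity_c = NULL,
                                  include_longevity = FALSE) {
  stopifnot(mc >= 0, mc <= 100)
  if (fecundity_c <= 0 || viability_c <= 0) {
    stop("control fecundity and viability must be positive")
  }
  r1 <- fecundity_t / fecundity_c
  r2 <- viability_t / viability_c
  r3 <- NA_real_
  prod <- r1 * r2
  if (include_longevity) {
    if (is.null(longevity_t) || is.null(longevity_c) ||
        is.na(longevity_t) || is.na(longevity_c)) {
      stop("longevities are required when include_longevity = TRUE")
    }
    if (longevity_c <= 0) stop("control longevity must be positive")
    r3 <- longevity_t / longevity_c
    prod <- prod * r3
  }
  ex_raw <- 100 - (100 - mc) * prod
  list(ex = clamp(ex_raw, 0, 100), ex_raw = ex_raw,
       mc = mc, R1 = r1, R2 = r2, R3 = r3)
}

IOBC_SCHEMES <- c("lab", "extended_lab")
IOBC_CLASSES <- c("I", "II", "III", "IV")

#' IOBC toxicity class from a reduction coefficient
#'
#' Laboratory scheme (topical exposure): I harmless (Ex < 30), II slightly
#' harmful (30 <= Ex < 80), III moderately harmful (80 <= Ex <= 99), IV
#' harmful (Ex > 99). Extended-laboratory scheme (aged residues): I
#' harmless (Ex < 25), II slightly harmful (25 <= Ex <= 50), III
#' moderately harmful (50 < Ex <= 75), IV harmful (Ex > 75). The published
#' band edges leave small gaps (79-80, 99 and 50-51); the half-open
#' intervals above close them, and every published (Ex, class) pair is
#' consistent with this resolution.
#'
#' @param ex reduction coefficient in percent, in `[0, 100]`.
#' @param scheme `"lab"` or `"extended_lab"`.
#' @return Factor level among `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
classify_iobc <- function(ex, scheme = c("lab", "extended_lab")) {
  scheme <- match.arg(scheme)
  stopifnot(all(ex >= 0), all(ex <= 100))
  cls <- if (scheme == "lab") {
    ifelse(ex < 30, "I", ifelse(ex < 80, "II", ifelse(ex <= 99, "III", "IV")))
  } else {
    ifelse(ex < 25, "I", ifelse(ex <= 50, "II", ifelse(ex <= 75, "III", "IV")))
  }
  factor(cls, levels = IOBC_CLASSES)
}

#' Score a treated cohort against its control
#'
#' Computes the full toxicity assessment for a treatment from raw cohort
#' records. For the `"egg"` variant, corrected mortality is the
#' Henderson-Tilton correction on pre-adult survival (initial eggs vs.
#' individuals reaching adulthood) and Ex includes the female longevity
#' ratio R3. For the `"adult"` variant, corrected mortality is computed on
#' 24-h survival after exposure (individuals with `death_age > 1` or
#' censored count as survivors) and Ex uses the two-factor form (R1, R2
#' only). Both use the laboratory IOBC scheme.
#'
#' @param control,treated validated [cohort()]s.
#' @param variant `"egg"` or `"adult"`.
#' @return Object of class `toxicity_assessment`: list with `treatment`,
#'   `variant`, `scheme`, `mc`, `R1`, `R2`, `R3`, `ex`, `ex_raw`, and
#'   `iobc_class`.
#' @export
score_cohort_pair <- function(control, treated, variant = c("egg", "adult")) {
  variant <- match.arg(variant)
  stopifnot(inherits(control, "cohort"), inherits(treated, "cohort"))
  n_adult <- function(ch) sum(vapply(ch$records, function(r) !is.na(r$nymph_end_age), logical(1)))
  n_alive_24h <- function(ch) sum(vapply(ch$records, function(r)
    is.na(r$death_age) || r$death_age > 1L, logical(1)))

  if (variant == "egg") {
    mc <- corrected_mortality(control$n_initial, n_adult(control),
                              treated$n_initial, n_adult(treated))
    sc <- cohort_summary(control)
    st <- cohort_summary(treated)
  } else {
    mc <- corrected_mortality(control$n_initial, n_alive_24h(control),
                              treated$n_initial, n_alive_24h(treated))
    # sublethal ratios are computed over the 24-h survivors, matching the
    # assay design (survivors are followed for fecundity and longevity)
    keep24 <- function(ch) {
      alive <- vapply(ch$records, function(r)
        is.na(r$death_age) || r$death_age > 1L, logical(1))
      structure(list(treatment = ch$treatment, n_initial = sum(alive),
                     records = ch$records[alive]), class = "cohort")
    }
    sc <- cohort_summary(keep24(control))
    st <- cohort_summary(keep24(treated))
  }
  if (is.na(sc$fecundity_per_female) || sc$fecundity_per_female <= 0 ||
      is.na(sc$viability_pct) || sc$viability_pct <= 0) {
    stop("control cohort has no reproducing females; ratios are undefined")
  }
  total_kill <- mc >= 100 ||
    (variant == "egg" && n_adult(treated) == 0) ||
    (variant == "adult" && n_alive_24h(treated) == 0)
  fec_t <- if (is.na(st$fecundity_per_female)) 0 else st$fecundity_per_female
  if (total_kill) {
    res <- list(ex = 100, ex_raw = 100, mc = 100, R1 = 0, R2 = NA_real_,
                R3 = NA_real_)
  } else if (fec_t <= 0) {
    # reproduction wiped out: R1 = 0 forces Ex = 100 whatever the other
    # ratios (which are undefined without surviving offspring)
    res <- list(ex = 100, ex_raw = 100, mc = mc, R1 = 0, R2 = NA_real_,
                R3 = NA_real_)
  } else {
    viab_t <- if (is.na(st$viability_pct)) 0 else st$viability_pct
    res <- reduction_coefficient(
      mc, fec_t, sc$fecundity_per_female, viab_t, sc$viability_pct,
      longevity_t = st$female_longevity, longevity_c = sc$female_longevity,
      include_longevity = (variant == "egg")
    )
  }
  structure(c(list(treatment = treated$treatment, variant = variant,
                   scheme = "lab"),
              res,
              list(iobc_class = classify_iobc(res$ex, "lab"))),
            class = "toxicity_assessment")
}

#' @export
print.toxicity_assessment <- function(x, ...) {
  cat(sprintf("<toxicity_assessment> %s (%s stage, %s scheme): Mc = %.2f%%, Ex = %.2f%% -> IOBC class %s\n",
              x$treatment, x$variant, x$scheme, x$mc, x$ex, as.character(x$iobc_class)))
  invisible(x)
}
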