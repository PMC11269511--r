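# Individual life-history records and treatment cohorts.
#
# A cohort is the unit of analysis throughout the package: one record per
# initial individual (egg or newly emerged adult), daily-census ages in
# whole days. Age 0 is the day of oviposition for egg-exposure cohorts and
# the day of adult emergence for adult-exposure cohorts.

EXPOSURE_ROUTES <- c("topical_egg", "topical_adult", "residual")
SEXES <- c("female", "male", "unknown")

#' Create a single life-history record
#'
#' One record describes the complete observed life history of one
#' individual in a treatment cohort: ages (in days) at which it left each
#' immature stage, its sex, age at death, daily egg counts, and
#' egg-viability trials for its offspring.
#'
#' Conventions: ages are integer days from the daily census. `hatch_age` is
#' the age at which the egg hatched (start of the larval stage);
#' `larva_end_age` the age at which the larva moulted to nymph;
#' `nymph_end_age` the age of adult emergence. A missing (`NA`) transition
#' age means the individual never reached that stage. `death_age` is the
#' age at the census on which the individual was first found dead; `NA`
#' means the individual was alive at the last census (right-censored).
#' Eggs that never hatch are recorded dead at age 4 with `hatch_age = NA`,
#' following the convention that an egg not hatching within 4 days is
#' considered dead.
#'
#' @param individual_id character identifier, unique within a cohort.
#' @param treatment character treatment label.
#' @param exposure_route one of `"topical_egg"`, `"topical_adult"`,
#'   `"residual"`.
#' @param hatch_age,larva_end_age,nymph_end_age integer stage-transition
#'   ages in days, or `NA` if the stage was never completed.
#' @param sex `"female"`, `"male"`, or `"unknown"` (unknown is only valid
#'   for individuals that died before adulthood, since immatures are not
#'   sexed).
#' @param death_age integer age at death in days, or `NA` if censored.
#' @param daily_eggs named integer vector of eggs laid per age; names are
#'   ages in days. Zero counts are dropped (they are implied).
#' @param viability_trials data frame with integer columns `eggs_tested`
#'   and `eggs_hatched`, one row per offspring viability trial.
#' @return An object of class `cohort_record`.
#' @seealso [cohort()], [validate_cohort()]
#' @export
cohort_record <- function(individual_id, treatment,
                          exposure_route = "topical_egg",
                          hatch_age = NA, larva_end_age = NA,
                          nymph_end_age = NA, sex = "unknown",
                          death_age = NA, daily_eggs = integer(),
                          viability_trials = NULL) {
  exposure_route <- match.arg(exposure_route, EXPOSURE_ROUTES)
  sex <- match.arg(sex, SEXES)
  if (is.null(viability_trials)) {
    viability_trials <- data.frame(eggs_tested = integer(), eggs_hatched = integer())
  }
  stopifnot(is.data.frame(viability_trials),
            all(c("eggs_tested", "eggs_hatched") %in% names(viability_trials)))
  viability_trials <- data.frame(
    eggs_tested = as.integer(viability_trials$eggs_tested),
    eggs_hatched = as.integer(viability_trials$eggs_hatched)
  )
  # canonical form for daily_eggs: positive counts only, sorted by age
  de <- as.integer(daily_eggs)
  names(de) <- names(daily_eggs)
  de <- de[!is.na(de) & de > 0]
  if (length(de)) de <- de[order(as.integer(names(de)))]
  names(de) <- as.character(as.integer(names(de)))

  structure(list(
    individual_id = as.character(individual_id),
    treatment = as.character(treatment),
    exposure_route = exposure_route,
    hatch_age = as.integer(hatch_age),
    larva_end_age = as.integer(larva_end_age),
    nymph_end_age = as.integer(nymph_end_age),
    sex = sex,
    death_age = as.integer(death_age),
    daily_eggs = de,
    viability_trials = viability_trials
  ), class = "cohort_record")
}

#' Create a treatment cohort
#'
#' Bundles the life-history records of every initial individual in one
#' treatment arm. Every individual that entered the experiment must have a
#' record (possibly dead at age 0), so the initial cohort size equals the
#' number of records.
#'
#' @param records list of [cohort_record()] objects sharing one treatment
#'   label.
#' @param treatment optional treatment label; defaults to the label of the
#'   records. Required when `records` is empty.
#' @return An object of class `cohort` with elements `treatment`,
#'   `n_initial` and `records`.
#' @export
cohort <- function(records, treatment = NULL) {
  stopifnot(is.list(records))
  if (length(records)) {
    stopifnot(all(vapply(records, inherits, logical(1), "cohort_record")))
    trts <- unique(vapply(records, function(r) r$treatment, character(1)))
    if (is.null(treatment)) {
      if (length(trts) != 1) {
        stop("records carry multiple treatment labels: ", paste(trts, collapse = ", "))
      }
      treatment <- trts
    }
  } else if (is.null(treatment)) {
    treatment <- NA_character_
  }
  structure(list(
    treatment = as.character(treatment),
    n_initial = length(records),
    records = records
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n_f <- sum(vapply(x$records, function(r) r$sex == "female", logical(1)))
  n_adult <- sum(vapply(x$records, function(r) !is.na(r$nymph_end_age), logical(1)))
  n_cens <- sum(vapply(x$records, function(r) is.na(r$death_age), logical(1)))
  cat(sprintf("<cohort> treatment '%s': %d individuals (%d reached adulthood, %d female, %d censored)\n",
              x$treatment, x$n_initial, n_adult, n_f, n_cens))
  invisible(x)
}

#' @export
print.cohort_record <- function(x, ...) {
  cat(sprintf("<cohort_record> %s [%s, %s] hatch=%s larva_end=%s adult=%s death=%s eggs=%d\n",
              x$individual_id, x$treatment, x$sex,
              x$hatch_age, x$larva_end_age, x$nymph_end_age, x$death_age,
              sum(x$daily_eggs)))
  invisible(x)
}

#' Validate a cohort against its structural invariants
#'
#' Checks every record for internal consistency: stage-transition ages must
#' be weakly increasing where defined, egg laying cannot precede adult
#' emergence, only adult females may have egg records, sex `"unknown"` is
#' only valid for individuals that died immature, and viability trials
#' cannot hatch more eggs than were tested. Violations are returned, not
#' thrown, so that file-derived cohorts can be triaged.
#'
#' @param x a [cohort()].
#' @return A data frame with columns `individual_id` and `rule`; zero rows
#'   when the cohort is valid.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  out <- list()
  add <- function(id, rule) out[[length(out) + 1L]] <<- data.frame(
    individual_id = id, rule = rule, stringsAsFactors = FALSE)

  if (x$n_initial != length(x$records)) {
    add("<cohort>", "n_initial must equal the number of records")
  }
  for (r in x$records) {
    id <- r$individual_id
    if (!identical(r$treatment, x$treatment)) {
      add(id, "record treatment differs from cohort treatment")
    }
    ages <- c(r$hatch_age, r$larva_end_age, r$nymph_end_age, r$death_age)
    known <- ages[!is.na(ages)]
    if (any(known < 0)) add(id, "ages must be non-negative")
    if (is.unsorted(known)) {
      add(id, "stage ages must satisfy hatch <= larva_end <= nymph_end <= death")
    }
    # transitions cannot skip: a defined later stage needs the earlier ones,
    # except adult-exposure cohorts which start at emergence (age 0)
    if (r$exposure_route != "topical_adult") {
      if (!is.na(r$larva_end_age) && is.na(r$hatch_age)) {
        add(id, "larva_end_age defined without hatch_age")
      }
      if (!is.na(r$nymph_end_age) && is.na(r$larva_end_age)) {
        add(id, "nymph_end_age defined without larva_end_age")
      }
    }
    if (length(r$daily_eggs)) {
      if (is.na(r$nymph_end_age)) {
        add(id, "daily_eggs recorded for an individual that never reached adulthood")
      } else if (any(as.integer(names(r$daily_eggs)) < r$nymph_end_age)) {
        add(id, "daily_eggs ages must be >= adult emergence age")
      }
      if (r$sex != "female") {
        add(id, "daily_eggs recorded for a non-female individual")
      }
      if (!is.na(r$death_age) &&
          any(as.integer(names(r$daily_eggs)) >= r$death_age)) {
        add(id, "daily_eggs recorded at or after death age")
      }
    }
    if (r$sex == "unknown" && !is.na(r$nymph_end_age)) {
      add(id, "sex 'unknown' is only valid for individuals that died immature")
    }
    vt <- r$viability_trials
    if (nrow(vt)) {
      if (any(vt$eggs_hatched > vt$eggs_tested)) {
        add(id, "eggs_hatched exceeds eggs_tested in a viability trial")
      }
      if (any(vt$eggs_tested < 0) || any(vt$eggs_hatched < 0)) {
        add(id, "viability counts must be non-negative")
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(individual_id = character(), rule = character(),
               stringsAsFactors = FALSE)
}

# last age at which a record is alive (death is observed at `death_age`,
# so the individual is alive through death_age - 1); censored individuals
# are alive through their last observed event age
last_alive_age <- function(r) {
  if (!is.na(r$death_age)) return(r$death_age - 1L)
  obs <- c(r$hatch_age, r$larva_end_age, r$nymph_end_age,
           if (length(r$daily_eggs)) max(as.integer(names(r$daily_eggs))) else NA,
           0L)
  max(obs, na.rm = TRUE)
}

# stage occupied at age x (only meaningful while alive); individuals dying
# within a stage keep that stage through their last alive day
stage_at_age <- function(r, x) {
  if (!is.na(r$nymph_end_age) && x >= r$nymph_end_age) {
    return(if (r$sex == "male") "male" else "female")
  }
  if (!is.na(r$larva_end_age) && x >= r$larva_end_age) return("nymph")
  if (!is.na(r$hatch_age) && x >= r$hatch_age) return("larva")
  "egg"
}
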