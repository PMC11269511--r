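# Extended-laboratory scoring of aged residues and IOBC persistence
# classification.
#
# A residue series follows one pesticide across residue ages (days after
# application): each time point gets a two-factor reduction coefficient
# and an extended-laboratory IOBC class; the series as a whole is then
# classified by how long the residues remain harmful:
#   A short-lived (< 5 days), B slightly persistent (5-15 days),
#   C moderately persistent (16-30 days), D highly persistent (> 30 days
#   or never harmless within the assessed window).

#' Score a residue-assay table into per-day assessments
#'
#' Takes the flat residue summary (see [read_residue_csv()]) containing a
#' control arm and treated arms per residue age, computes for each treated
#' arm and day: corrected mortality (taken as-is when `is_corrected`,
#' otherwise Abbott-corrected against the same-day control), the fecundity
#' ratio R1 and viability ratio R2 against the same-day control, the
#' two-factor reduction coefficient, and the extended-laboratory IOBC
#' class.
#'
#' @param assays data frame in the residue-assay layout.
#' @param control label of the control treatment within `assays`.
#' @return A `residue_series_set`: named list (one `residue_series` per
#'   treatment), each a data frame with columns `days_after_application`,
#'   `mc`, `R1`, `R2`, `ex`, `ex_raw`, `iobc_class`.
#' @export
assess_residue_series <- function(assays, control = "control") {
  need <- c("treatment", "days_after_application", "mortality_pct",
            "is_corrected", "fecundity_per_female", "viability_pct")
  stopifnot(is.data.frame(assays), all(need %in% names(assays)))
  ctrl <- assays[assays$treatment == control, ]
  if (!nrow(ctrl)) stop("control treatment '", control, "' not found in assays")
  trts <- setdiff(unique(assays$treatment), control)
  out <- lapply(trts, function(tr) {
    rows <- assays[assays$treatment == tr, ]
    rows <- rows[order(rows$days_after_application), ]
    if (anyDuplicated(rows$days_after_application)) {
      stop("duplicate residue age for treatment '", tr, "'")
    }
    res <- lapply(seq_len(nrow(rows)), function(i) {
      day <- rows$days_after_application[i]
      c0 <- ctrl[ctrl$days_after_application == day, ]
      if (nrow(c0) != 1) {
        stop("no (or ambiguous) control row at ", day, " days for '", tr, "'")
      }
      mc <- if (isTRUE(rows$is_corrected[i])) {
        clamp(rows$mortality_pct[i], 0, 100)
      } else {
        abbott_mortality(rows$mortality_pct[i], c0$mortality_pct)
      }
      if (mc >= 100) {
        data.frame(days_after_application = day, mc = 100, R1 = 0,
                   R2 = NA_real_, ex = 100, ex_raw = 100,
                   iobc_class = "IV", stringsAsFactors = FALSE)
      } else {
        rc <- reduction_coefficient(mc, rows$fecundity_per_female[i],
                                    c0$fecundity_per_female,
                                    rows$viability_pct[i], c0$viability_pct)
        data.frame(days_after_application = day, mc = mc, R1 = rc$R1,
                   R2 = rc$R2, ex = rc$ex, ex_raw = rc$ex_raw,
                   iobc_class = as.character(classify_iobc(rc$ex, "extended_lab")),
                   stringsAsFactors = FALSE)
      }
    })
    structure(do.call(rbind, res),
              treatment = tr, scheme = "extended_lab",
              class = c("residue_series", "data.frame"))
  })
  names(out) <- trts
  structure(out, class = "residue_series_set")
}

#' Classify the persistence of a pesticide residue series
#'
#' Determines the earliest assessed residue age at which the pesticide is
#' harmless (extended-laboratory class I) with no harmful assessment at
#' any later age, then assigns the IOBC persistence class: A if that age
#' is under 5 days, B for 5-15 days, C for 16-30 days, and D if residues
#' are still harmful past 30 days or never become harmless within the
#' series. A series that reverts from harmless back to harmful
#' (non-monotone recovery) is classified from the last transition and a
#' warning is emitted.
#'
#' @param series a `residue_series` from [assess_residue_series()], or any
#'   data frame with columns `days_after_application` and `iobc_class`.
#' @return Object of class `persistence_result`: list with
#'   `persistence_class` (`"A"`, `"B"`, `"C"`, `"D"`), `days_to_harmless`
#'   (integer or `NA`), and `nonmonotone` flag.
#' @export
assess_persistence <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("days_after_application", "iobc_class") %in% names(series)))
  if (!nrow(series)) stop("residue series is empty")
  series <- series[order(series$days_after_application), ]
  days <- series$days_after_application
  if (any(days <= 0)) stop("days_after_application must be positive")
  harmless <- as.character(series$iobc_class) == "I"

  nonmono <- FALSE
  if (any(harmless) && any(!harmless)) {
    # non-monotone: some harmless day followed by a harmful one
    nonmono <- max(which(!harmless)) > min(which(harmless))
    if (nonmono) {
      warning("non-monotone recovery in residue series; classifying from the last harmless transition")
    }
  }
  last_harmful <- if (any(!harmless)) max(which(!harmless)) else 0L
  days_to_harmless <- if (last_harmful < length(days)) {
    as.integer(days[last_harmful + 1L])
  } else {
    NA_integer_     # never harmless within the assessed window
  }
  cls <- if (is.na(days_to_harmless) || days_to_harmless > 30) {
    "D"
  } else if (days_to_harmless >= 16) {
    "C"
  } else if (days_to_harmless >= 5) {
    "B"
  } else {
    "A"
  }
  structure(list(persistence_class = factor(cls, levels = c("A", "B", "C", "D")),
                 days_to_harmless = days_to_harmless,
                 nonmonotone = nonmono),
            class = "persistence_result")
}

#' @export
print.persistence_result <- function(x, ...) {
  lab <- c(A = "short-lived (< 5 days)", B = "slightly persistent (5-15 days)",
           C = "moderately persistent (16-30 days)", D = "highly persistent (> 30 days)")
  cat(sprintf("<persistence_result> class %s: %s; harmless from day %s\n",
              as.character(x$persistence_class),
              lab[[as.character(x$persistence_class)]],
              ifelse(is.na(x$days_to_harmless), "never (within series)",
                     x$days_to_harmless)))
  invisible(x)
}
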