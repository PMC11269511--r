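# Cohort file I/O: a long "event" CSV, one row per recorded event.
#
# Columns: individual_id, treatment, event_type, age_day, value.
# Event types:
#   route            value = exposure route (always present, once per individual)
#   sex              value = female/male/unknown
#   hatch, larva_end, nymph_end, death   age_day = transition/death age
#   eggs             age_day = age, value = eggs laid that day (> 0)
#   viability_tested / viability_hatched age_day = trial index, value = count
# Lines starting with '#' are comments; the writer emits a versioned header.

COHORT_CSV_HEADER <- "# demotox cohort events v1"
.cohort_csv_cols <- c("individual_id", "treatment", "event_type", "age_day", "value")

#' Write a cohort to a long-format event CSV
#'
#' @param x a [cohort()].
#' @param path output file path (UTF-8, comma separated, '.' decimal).
#' @return `path`, invisibly.
#' @seealso [read_cohort_csv()] for the inverse; the two round-trip exactly.
#' @export
write_cohort_csv <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  rows <- list(paste(.cohort_csv_cols, collapse = ","))
  emit <- function(id, trt, type, age, value) {
    rows[[length(rows) + 1L]] <<- paste(id, trt, type,
                                        ifelse(is.na(age), "", age),
                                        ifelse(is.na(value), "", value), sep = ",")
  }
  for (r in x$records) {
    if (grepl("[,\n]", r$individual_id) || grepl("[,\n]", r$treatment)) {
      stop("individual_id and treatment labels must not contain commas")
    }
    emit(r$individual_id, r$treatment, "route", NA, r$exposure_route)
    emit(r$individual_id, r$treatment, "sex", NA, r$sex)
    if (!is.na(r$hatch_age)) emit(r$individual_id, r$treatment, "hatch", r$hatch_age, NA)
    if (!is.na(r$larva_end_age)) emit(r$individual_id, r$treatment, "larva_end", r$larva_end_age, NA)
    if (!is.na(r$nymph_end_age)) emit(r$individual_id, r$treatment, "nymph_end", r$nymph_end_age, NA)
    if (!is.na(r$death_age)) emit(r$individual_id, r$treatment, "death", r$death_age, NA)
    for (a in names(r$daily_eggs)) {
      emit(r$individual_id, r$treatment, "eggs", a, r$daily_eggs[[a]])
    }
    vt <- r$viability_trials
    for (i in seq_len(nrow(vt))) {
      emit(r$individual_id, r$treatment, "viability_tested", i, vt$eggs_tested[i])
      emit(r$individual_id, r$treatment, "viability_hatched", i, vt$eggs_hatched[i])
    }
  }
  writeLines(c(COHORT_CSV_HEADER, unlist(rows)), path, useBytes = TRUE)
  invisible(path)
}

#' Read a cohort from a long-format event CSV
#'
#' Reconstructs exactly what [write_cohort_csv()] emitted. Parse errors
#' report the offending line number; duplicate events for the same
#' individual and age are rejected.
#'
#' @param path file path.
#' @return A [cohort()].
#' @export
read_cohort_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no header row found in ", path)
  header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), .cohort_csv_cols)) {
    stop("unexpected header on line ", lineno[1], ": ", lines[[1]])
  }
  body <- lines[-1]
  body_no <- lineno[-1]

  events <- list()   # per individual: list of parsed event rows
  order_ids <- character()
  seen <- new.env(parent = emptyenv())   # duplicate detection

  for (k in seq_along(body)) {
    f <- strsplit(body[[k]], ",", fixed = TRUE)[[1]]
    length(f) <- 5L
    if (is.na(f[1]) || is.na(f[3]) || !nzchar(f[1]) || !nzchar(f[3])) {
      stop("malformed row on line ", body_no[k], ": ", body[[k]])
    }
    id <- f[1]; trt <- f[2]; type <- f[3]
    age <- if (!is.na(f[4]) && nzchar(f[4])) suppressWarnings(as.integer(f[4])) else NA_integer_
    if (!is.na(f[4]) && nzchar(f[4]) && is.na(age)) {
      stop("non-integer age_day on line ", body_no[k], ": ", body[[k]])
    }
    if (!is.na(age) && age < 0) {
      stop("negative age_day on line ", body_no[k], ": ", body[[k]])
    }
    key <- paste(id, type, age, sep = "\r")
    if (!is.null(seen[[key]])) {
      stop("duplicate event for individual '", id, "' (", type,
           ", age ", age, ") on line ", body_no[k])
    }
    seen[[key]] <- TRUE
    if (!id %in% order_ids) {
      order_ids <- c(order_ids, id)
      events[[id]] <- list()
    }
    events[[id]][[length(events[[id]]) + 1L]] <-
      list(treatment = trt, type = type, age = age, value = f[5])
  }

  records <- lapply(order_ids, function(id) {
    ev <- events[[id]]
    get1 <- function(type) {
      m <- Filter(function(e) e$type == type, ev)
      if (length(m)) m[[1]] else NULL
    }
    num <- function(e) if (is.null(e)) NA_integer_ else e$age
    route <- get1("route")
    sexev <- get1("sex")
    eggs_ev <- Filter(function(e) e$type == "eggs", ev)
    de <- vapply(eggs_ev, function(e) as.integer(e$value), integer(1))
    names(de) <- vapply(eggs_ev, function(e) as.character(e$age), character(1))
    vt_t <- Filter(function(e) e$type == "viability_tested", ev)
    vt_h <- Filter(function(e) e$type == "viability_hatched", ev)
    idx_t <- vapply(vt_t, function(e) e$age, integer(1))
    idx_h <- vapply(vt_h, function(e) e$age, integer(1))
    if (!setequal(idx_t, idx_h)) {
      stop("unpaired viability rows for individual '", id, "'")
    }
    vt <- data.frame(
      eggs_tested = vapply(vt_t[order(idx_t)], function(e) as.integer(e$value), integer(1)),
      eggs_hatched = vapply(vt_h[order(idx_h)], function(e) as.integer(e$value), integer(1))
    )
    cohort_record(
      individual_id = id,
      treatment = ev[[1]]$treatment,
      exposure_route = if (is.null(route)) "topical_egg" else route$value,
      hatch_age = num(get1("hatch")),
      larva_end_age = num(get1("larva_end")),
      nymph_end_age = num(get1("nymph_end")),
      sex = if (is.null(sexev)) "unknown" else sexev$value,
      death_age = num(get1("death")),
      daily_eggs = de,
      viability_trials = vt
    )
  })
  cohort(records)
}

#' Read or write residue-assay summary tables
#'
#' Residue (extended-laboratory) assays are consumed as flat summaries, one
#' row per treatment and residue age: percent adult mortality after the
#' exposure window, whether that mortality is already control-corrected,
#' eggs per surviving female, and percent egg viability.
#'
#' @param path CSV file path.
#' @return `read_residue_csv()` returns a data frame with columns
#'   `treatment`, `days_after_application`, `mortality_pct`,
#'   `is_corrected`, `fecundity_per_female`, `viability_pct`.
#' @export
read_residue_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("treatment", "days_after_application", "mortality_pct",
            "is_corrected", "fecundity_per_female", "viability_pct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("residue CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df$is_corrected <- as.logical(df$is_corrected)
  bad <- df$days_after_application <= 0
  if (any(bad)) stop("days_after_application must be positive")
  if (any(df$mortality_pct < 0 | df$mortality_pct > 100, na.rm = TRUE) ||
      any(df$viability_pct < 0 | df$viability_pct > 100, na.rm = TRUE)) {
    stop("percentages must lie in [0, 100]")
  }
  if (any(df$fecundity_per_female < 0, na.rm = TRUE)) {
    stop("fecundity_per_female must be non-negative")
  }
  df[need]
}

#' @rdname read_residue_csv
#' @param x data frame in the residue-assay layout.
#' @export
write_residue_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
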