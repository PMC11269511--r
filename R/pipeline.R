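# End-to-end report pipeline: cohort CSVs (and optionally a residue-assay
# CSV) in, the four standard report tables out, with a structured log so
# every reported number can be traced to a module call and seed.

#' Build a pipeline configuration
#'
#' @param cohorts named list: treatment label -> cohort CSV path or
#'   [cohort()] object. Must include the control.
#' @param control label of the control treatment.
#' @param residue_assays optional residue-assay CSV path or data frame
#'   (see [read_residue_csv()]); its control arm must be labelled
#'   `control` too.
#' @param B bootstrap replicates for SEs and paired tests (>= 100).
#' @param seed integer root seed for all resampling.
#' @param out_dir output directory for report files, or `NULL` to skip
#'   writing.
#' @param mortality_cutoff_pct treatments whose immature mortality is at
#'   or above this percentage are excluded from the demographic-parameter
#'   report (their life table is degenerate) but still scored for Ex.
#' @param variant exposure variant for toxicity scoring (`"egg"` or
#'   `"adult"`), applied to cohorts whose records do not carry a route.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohorts, control, residue_assays = NULL,
                            B = 1000L, seed = 1L, out_dir = NULL,
                            mortality_cutoff_pct = 85,
                            variant = c("egg", "adult")) {
  variant <- match.arg(variant)
  stopifnot(is.list(cohorts), length(cohorts) >= 1, !is.null(names(cohorts)))
  if (!control %in% names(cohorts)) {
    stop("control treatment '", control, "' is not among the cohorts")
  }
  if (B < 100) stop("B must be at least 100")
  structure(list(cohorts = cohorts, control = control,
                 residue_assays = residue_assays,
                 B = as.integer(B), seed = as.integer(seed),
                 out_dir = out_dir,
                 mortality_cutoff_pct = mortality_cutoff_pct,
                 variant = variant),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Expected fields mirror [pipeline_config()]: `cohorts` (map label ->
#' CSV path), `control`, optional `residue_assays` path, `B`, `seed`,
#' `out_dir`, `mortality_cutoff_pct`, `variant`. Relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.character(p) && !file.exists(p)) file.path(base, p) else p
  cohorts <- lapply(y$cohorts, resolve)
  pipeline_config(
    cohorts = cohorts,
    control = y$control,
    residue_assays = if (!is.null(y$residue_assays)) resolve(y$residue_assays) else NULL,
    B = y$B %||% 1000L,
    seed = y$seed %||% 1L,
    out_dir = y$out_dir %||% NULL,
    mortality_cutoff_pct = y$mortality_cutoff_pct %||% 85,
    variant = y$variant %||% "egg"
  )
}

load_cohort_input <- function(x, label) {
  ch <- if (inherits(x, "cohort")) x else read_cohort_csv(x)
  v <- validate_cohort(ch)
  if (nrow(v)) {
    stop("cohort '", label, "' failed validation: ",
         paste(unique(v$rule), collapse = "; "))
  }
  ch
}

#' Run the full reporting pipeline
#'
#' Produces the four standard report tables of a pesticide life-table
#' response study:
#' \describe{
#'   \item{stage_table}{per-treatment stage durations and survival.}
#'   \item{toxicity_table}{corrected mortality, fecundity, viability,
#'     longevities, reduction coefficient Ex and laboratory IOBC class per
#'     treatment.}
#'   \item{demographic_table}{R0, r, lambda, T with bootstrap SEs and the
#'     paired-bootstrap p-value against the control, for treatments whose
#'     immature mortality is below the configured cutoff.}
#'   \item{persistence_table}{per-residue-age Ex/class and the persistence
#'     class, when residue assays are supplied.}
#' }
#' All numbers are recomputed from the raw records; the returned `log`
#' records every module call with its seed, and the same configuration and
#' seed always reproduce identical output. When `out_dir` is set, tables
#' are written as TSV plus a combined JSON report and the log as text.
#'
#' @param config a [pipeline_config()] or path to a YAML file for
#'   [read_pipeline_config()].
#' @return Object of class `pipeline_report`: list with the four tables
#'   (those not applicable are `NULL`), `demographic_estimates` (the
#'   underlying `bootstrap_estimate` objects), and `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }

  logf("pipeline start: %d cohort(s), control '%s', B = %d, seed = %d",
       length(config$cohorts), config$control, config$B, config$seed)
  cohorts <- Map(load_cohort_input, config$cohorts, names(config$cohorts))
  names(cohorts) <- names(config$cohorts)
  # deterministic treatment order: control first, then sorted labels
  trts <- c(config$control,
            sort(setdiff(names(cohorts), config$control)))
  cohorts <- cohorts[trts]
  for (tr in trts) logf("loaded cohort '%s' (n = %d)", tr, cohorts[[tr]]$n_initial)

  ## (a) stage-duration / survival table
  stage_table <- do.call(rbind, lapply(cohorts, cohort_summary))
  rownames(stage_table) <- NULL
  logf("stage table: %d treatment(s) via cohort_summary", nrow(stage_table))

  ## (b) toxicity table (every non-control treatment)
  control_cohort <- cohorts[[config$control]]
  treated_names <- setdiff(trts, config$control)
  toxicity_table <- NULL
  if (length(treated_names)) {
    rows <- lapply(treated_names, function(tr) {
      route <- if (length(cohorts[[tr]]$records)) {
        cohorts[[tr]]$records[[1]]$exposure_route
      } else {
        "topical_egg"
      }
      variant <- if (route == "topical_adult") "adult" else config$variant
      a <- score_cohort_pair(control_cohort, cohorts[[tr]], variant)
      logf("toxicity '%s' (%s variant): Mc = %.2f, Ex = %.2f, class %s",
           tr, variant, a$mc, a$ex, as.character(a$iobc_class))
      s <- cohort_summary(cohorts[[tr]])
      data.frame(treatment = tr, variant = variant,
                 mc = round_half_up(a$mc, 2),
                 fecundity_per_female = round_half_up(s$fecundity_per_female, 1),
                 viability_pct = round_half_up(s$viability_pct, 1),
                 female_longevity = round_half_up(s$female_longevity, 1),
                 male_longevity = round_half_up(s$male_longevity, 1),
                 ex = round_half_up(a$ex, 2),
                 iobc_class = as.character(a$iobc_class),
                 stringsAsFactors = FALSE)
    })
    toxicity_table <- do.call(rbind, rows)
  }

  ## (c) demographic-parameter table with bootstrap SEs and paired tests
  immature_mortality <- vapply(trts, function(tr) {
    s <- stage_table[stage_table$treatment == tr, ]
    100 - s$preadult_survival_pct
  }, numeric(1))
  eligible <- trts[immature_mortality < config$mortality_cutoff_pct]
  excluded <- setdiff(trts, eligible)
  for (tr in excluded) {
    logf("'%s' excluded from demographic table (immature mortality %.1f%% >= %.1f%%)",
         tr, immature_mortality[[tr]], config$mortality_cutoff_pct)
  }
  params <- c("R0", "r", "lambda", "T")
  demographic_estimates <- list()
  demo_rows <- list()
  for (tr in eligible) {
    est <- lapply(params, function(p) {
      bootstrap_estimate(cohorts[[tr]], p, B = config$B, seed = config$seed)
    })
    names(est) <- params
    demographic_estimates[[tr]] <- est
    logf("bootstrap SEs for '%s' (B = %d, seed = %d, n_failed: %s)",
         tr, config$B, config$seed,
         paste(vapply(est, function(e) e$n_failed, integer(1)), collapse = "/"))
    row <- data.frame(treatment = tr, stringsAsFactors = FALSE)
    for (p in params) {
      digits <- if (p %in% c("r", "lambda")) 3 else 2
      row[[p]] <- round_half_up(est[[p]]$point, digits)
      row[[paste0(p, "_se")]] <- round_half_up(est[[p]]$se, digits)
      if (tr != config$control) {
        tst <- paired_bootstrap_test(cohorts[[tr]], control_cohort, p,
                                     B = config$B, seed = config$seed)
        row[[paste0(p, "_p_vs_control")]] <- tst$p_value
        row[[paste0(p, "_differs")]] <- tst$p_value < 0.05
        logf("paired test '%s' vs control on %s: p = %.4g", tr, p, tst$p_value)
      } else {
        row[[paste0(p, "_p_vs_control")]] <- NA_real_
        row[[paste0(p, "_differs")]] <- NA
      }
    }
    demo_rows[[tr]] <- row
  }
  demographic_table <- if (length(demo_rows)) {
    out <- do.call(rbind, demo_rows); rownames(out) <- NULL; out
  } else {
    NULL
  }

  ## (d) persistence table
  persistence_table <- NULL
  if (!is.null(config$residue_assays)) {
    assays <- if (is.data.frame(config$residue_assays)) {
      config$residue_assays
    } else {
      read_residue_csv(config$residue_assays)
    }
    series_set <- assess_residue_series(assays, control = config$control)
    rows <- lapply(names(series_set), function(tr) {
      ser <- series_set[[tr]]
      pers <- assess_persistence(ser)
      logf("persistence '%s': class %s (harmless from day %s)", tr,
           as.character(pers$persistence_class),
           ifelse(is.na(pers$days_to_harmless), "never", pers$days_to_harmless))
      data.frame(treatment = tr,
                 day = ser$days_after_application,
                 mc = round_half_up(ser$mc, 1),
                 ex = round_half_up(ser$ex, 1),
                 iobc_class = ser$iobc_class,
                 persistence_class = as.character(pers$persistence_class),
                 days_to_harmless = pers$days_to_harmless,
                 stringsAsFactors = FALSE)
    })
    persistence_table <- do.call(rbind, rows)
  }

  logf("pipeline complete")
  report <- structure(list(
    stage_table = stage_table,
    toxicity_table = toxicity_table,
    demographic_table = demographic_table,
    persistence_table = persistence_table,
    demographic_estimates = demographic_estimates,
    log = log_lines,
    config = config
  ), class = "pipeline_report")

  if (!is.null(config$out_dir)) write_pipeline_report(report, config$out_dir)
  report
}

#' Write a pipeline report bundle to disk
#'
#' Emits each table as TSV, a combined machine-readable `report.json`, and
#' the computation log as `log.txt`.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("stage_table", "toxicity_table", "demographic_table",
            "persistence_table")
  for (tb in tabs) {
    if (!is.null(report[[tb]])) {
      utils::write.table(report[[tb]], file.path(out_dir, paste0(tb, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  json <- report[tabs]
  json <- json[!vapply(json, is.null, logical(1))]
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE,
                       digits = NA)
  writeLines(report$log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  stage_table:        %d treatment(s)\n", nrow(x$stage_table)))
  cat(sprintf("  toxicity_table:     %s\n",
              if (is.null(x$toxicity_table)) "none" else paste(nrow(x$toxicity_table), "treatment(s)")))
  cat(sprintf("  demographic_table:  %s\n",
              if (is.null(x$demographic_table)) "none" else paste(nrow(x$demographic_table), "treatment(s)")))
  cat(sprintf("  persistence_table:  %s\n",
              if (is.null(x$persistence_table)) "none" else paste(nrow(x$persistence_table), "row(s)")))
  cat(sprintf("  log: %d line(s)\n", length(x$log)))
  invisible(x)
}
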