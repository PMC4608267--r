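#' Pipeline run configuration
#'
#' @param cutoff_pct accuracy cutoff, percent (5 by default; 2.5 is the
#'   stricter alternative)
#' @param eq_ids equations to evaluate
#' @param by_sex include the per-sex metric tables in reports
#' @param fit_new also run [forward_select()] on the cohort and report the fit
#' @param candidates candidate terms when `fit_new` is `TRUE`
#' @param out_dir directory for report files (`NULL`: no files written)
#' @param seed seed recorded in the report (and used for simulation when the
#'   pipeline generates its own cohort)
#' @return list of class `run_config`
#' @export
run_config <- function(cutoff_pct = 5, eq_ids = equation_ids(), by_sex = TRUE,
                       fit_new = FALSE, candidates = DEFAULT_CANDIDATES,
                       out_dir = NULL, seed = 1L) {
  stopifnot(cutoff_pct > 0)
  structure(list(cutoff_pct = cutoff_pct, eq_ids = eq_ids, by_sex = by_sex,
                 fit_new = fit_new, candidates = candidates,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the validation pipeline on a cohort
#'
#' Predict with every configured equation, compute the accuracy metrics
#' overall (and by sex), rank the equations, optionally develop a new
#' equation by forward selection, and write TSV/JSON reports. The run log
#' accounts for every subject and equation excluded and why
#' (n_in = n_used + n_rejected).
#'
#' @param cohort a `bia_cohort` (e.g. from [read_cohort()] or
#'   [generate_cohort()])
#' @param config a [run_config()]
#' @return list of class `bia_run`: `validation` (a `bia_validation`),
#'   `fit` (an `ffm_fit` or `NULL`), `log` (accounting tibbles), and the
#'   paths of any files written
#' @export
run_pipeline <- function(cohort, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  validation <- validate_equations(cohort, config$eq_ids, config$cutoff_pct)
  fit <- if (config$fit_new) forward_select(cohort, config$candidates,
                                            cutoff_pct = config$cutoff_pct)
         else NULL

  log <- list(
    n_in = nrow(cohort) + nrow(cohort_issues(cohort)),
    n_used = nrow(cohort),
    rejected_rows = cohort_issues(cohort),
    skipped_pairs = validation$skipped,
    excluded_equations = validation$excluded_eqs
  )

  paths <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- write_validation_report(validation, config$out_dir, fit = fit,
                                     by_sex = config$by_sex, seed = config$seed)
  }
  structure(list(validation = validation, fit = fit, log = log, paths = paths),
            class = "bia_run")
}

#' @export
print.bia_run <- function(x, ...) {
  cat("<bia_run> n_in =", x$log$n_in, " n_used =", x$log$n_used,
      " rejected =", nrow(x$log$rejected_rows), "\n")
  print(x$validation)
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' Write validation reports to disk
#'
#' Writes `metrics.tsv` (rendered like the study's evaluation table:
#' percentages and kg to one decimal) plus `report.json` with full-precision
#' metrics, the per-sex tables, ranking trace and run accounting. Output is
#' deterministic: identical inputs give byte-identical files.
#'
#' @param validation a `bia_validation`
#' @param out_dir output directory
#' @param fit optional `ffm_fit` to embed
#' @param by_sex include per-sex tables
#' @param seed seed to record
#' @return character vector of the files written
#' @export
write_validation_report <- function(validation, out_dir, fit = NULL,
                                    by_sex = TRUE, seed = NA_integer_) {
  tsv <- file.path(out_dir, "metrics.tsv")
  rendered <- format_metrics_table(validation$overall)
  write.table(rendered, tsv, sep = "\t", row.names = FALSE, quote = FALSE)

  payload <- list(
    cutoff_pct = validation$cutoff_pct,
    n_subjects = validation$n_subjects,
    best_eq_id = validation$best_eq_id,
    overall = validation$overall,
    by_sex = if (by_sex) validation$by_sex else NULL,
    ranking_trace = validation$ranking_trace,
    skipped = validation$skipped,
    excluded_equations = validation$excluded_eqs,
    seed = seed
  )
  if (!is.null(fit)) {
    payload$fit <- list(terms = fit$terms,
                        coefficients = as.list(fit$coefficients),
                        r2 = fit$r2, see_kg = fit$see_kg, n = fit$n,
                        internal_pct_accurate = fit$internal_pct_accurate)
  }
  json <- file.path(out_dir, "report.json")
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  c(tsv, json)
}
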