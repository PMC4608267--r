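# Candidate predictors offered when developing a new FFM equation:
# weight, age, height, BMI, the resistance and impedance indices, raw
# electrical quantities, sex (male = 1, female = 0) and the pubertal dummy.
# BMI-SDS joins only when supplied as a column.
DEFAULT_CANDIDATES <- c("W", "AGE", "H", "BMI", "H2_over_R", "H2_over_Z",
                        "R", "Z", "X", "SEX01", "TANNER2")

design_frame <- function(cohort, terms, response = "ffm_dxa_kg") {
  y <- cohort[[response]]
  X <- build_terms(cohort, terms)
  df <- cbind(data.frame(.y = y), as.data.frame(X))
  keep <- complete.cases(df)
  list(df = df[keep, , drop = FALSE], n_dropped = sum(!keep))
}

#' Ordinary least squares fit of FFM on chosen predictor terms
#'
#' Fits `ffm_dxa_kg` on the given term tags by least squares and reports the
#' quantities used when developing a BIA equation: coefficients, \eqn{R^2},
#' the standard error of estimate \eqn{SEE = \sqrt{SSE/(n - p - 1)}} (p =
#' number of slope terms), and the internal accuracy (percentage of subjects
#' whose fitted FFM falls within the cutoff of their DXA FFM, via
#' [compute_metrics()]).
#'
#' @param cohort cohort with `ffm_dxa_kg` and the fields the terms need
#' @param terms character vector of predictor tags (see [build_terms()])
#' @param cutoff_pct cutoff for the internal accuracy, percent
#' @return object of class `ffm_fit`: list with `terms`, `coefficients`
#'   (named, `intercept` last), `r2`, `see_kg`, `n`, `n_dropped`,
#'   `internal_pct_accurate`, `coef_table` (estimates, SEs, t, p; p-values
#'   are reported, never used for selection), `fitted`, `residuals`
#' @export
fit_ols <- function(cohort, terms, cutoff_pct = 5) {
  cohort <- tibble::as_tibble(as.data.frame(cohort))
  stopifnot(length(terms) >= 1L)
  d <- design_frame(cohort, terms)
  df <- d$df
  n <- nrow(df)
  p <- length(terms)
  if (n <= p + 1L) {
    stop("need n > p + 1 complete observations (n = ", n, ", p = ", p, ")",
         call. = FALSE)
  }

  fit <- lm(.y ~ ., data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design: collinear term(s) ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }

  res <- fit$residuals
  sse <- sum(res^2)
  sst <- sum((df$.y - mean(df$.y))^2)
  r2 <- 1 - sse / sst
  see <- sqrt(sse / (n - p - 1))
  acc <- compute_metrics(fit$fitted.values, df$.y, cutoff_pct)$pct_accurate

  sm <- suppressWarnings(summary(fit))$coefficients  # noiseless fits are legitimate
  coefs <- c(cf[-1L], intercept = unname(cf[1L]))

  structure(
    list(response = "ffm_dxa_kg", terms = terms, coefficients = coefs,
         r2 = r2, see_kg = see, n = n, n_dropped = d$n_dropped,
         internal_pct_accurate = acc,
         coef_table = tibble::tibble(
           term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
           t_value = sm[, 3], p_value = sm[, 4]),
         fitted = unname(fit$fitted.values), residuals = unname(res)),
    class = "ffm_fit")
}

#' @export
print.ffm_fit <- function(x, ...) {
  eqn <- paste(sprintf("%.3f*%s", x$coefficients[x$terms], x$terms),
               collapse = " + ")
  cat("<ffm_fit> FFM =", eqn,
      sprintf("%+.3f", x$coefficients[["intercept"]]), "\n")
  cat(sprintf("  n = %d, R2 = %.3f, SEE = %.2f kg, internal accuracy = %.1f%%\n",
              x$n, x$r2, x$see_kg, x$internal_pct_accurate))
  if (!is.null(x$selection_trace)) {
    cat("  forward selection:",
        paste(sprintf("%s (R2 %.3f)", x$selection_trace$term,
                      x$selection_trace$r2), collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Greedy forward selection of FFM predictors
#'
#' At each step the candidate term giving the largest \eqn{R^2} when added
#' to the current model is adopted, provided the improvement is at least
#' `threshold`; selection stops otherwise. Selection is on explained
#' variance only. Candidates whose addition leaves the design rank-deficient
#' contribute no improvement and are never adopted.
#'
#' @param cohort cohort with `ffm_dxa_kg`
#' @param candidates candidate term tags (default [DEFAULT_CANDIDATES];
#'   tags whose fields are entirely missing are dropped with a message)
#' @param threshold minimum \eqn{R^2} improvement to accept a step
#' @param cutoff_pct cutoff for the internal accuracy, percent
#' @return an `ffm_fit` with `selection_trace`, a tibble of
#'   `(step, term, r2, delta_r2)` for each accepted step. If no candidate
#'   improves on the intercept-only model, an intercept-only fit is returned
#'   with a warning.
#' @export
forward_select <- function(cohort, candidates = DEFAULT_CANDIDATES,
                           threshold = 0.01, cutoff_pct = 5) {
  cohort <- tibble::as_tibble(as.data.frame(cohort))
  usable <- candidates[vapply(candidates, function(tag) {
    flds <- term_required_fields(tag)
    all(flds %in% names(cohort)) && any(complete.cases(cohort[flds]))
  }, logical(1))]
  dropped <- setdiff(candidates, usable)
  if (length(dropped)) {
    message("dropping candidate(s) with no data: ", paste(dropped, collapse = ", "))
  }
  if (!length(usable)) stop("no usable candidate predictors", call. = FALSE)

  # complete cases over the full candidate field set, so every step
  # compares models on the same subjects
  d <- design_frame(cohort, usable)
  df <- d$df

  r2_of <- function(tags) {
    f <- lm(.y ~ ., data = df[c(".y", tags)])
    if (anyNA(coef(f))) return(NA_real_)  # rank-deficient: no usable gain
    1 - sum(f$residuals^2) / sum((df$.y - mean(df$.y))^2)
  }

  selected <- character()
  r2_cur <- 0
  trace <- list()
  repeat {
    remaining <- setdiff(usable, selected)
    if (!length(remaining)) break
    r2_try <- vapply(remaining, function(tag) r2_of(c(selected, tag)), numeric(1))
    if (all(is.na(r2_try))) break
    best <- remaining[which.max(r2_try)]
    gain <- max(r2_try, na.rm = TRUE) - r2_cur
    if (gain < threshold) break
    selected <- c(selected, best)
    r2_cur <- max(r2_try, na.rm = TRUE)
    trace[[length(trace) + 1L]] <- tibble::tibble(
      step = length(selected), term = best, r2 = r2_cur, delta_r2 = gain)
  }

  if (!length(selected)) {
    warning("no candidate improves R2 by >= ", threshold,
            "; returning intercept-only fit", call. = FALSE)
    y <- df$.y
    fit <- structure(
      list(response = "ffm_dxa_kg", terms = character(),
           coefficients = c(intercept = mean(y)), r2 = 0,
           see_kg = sqrt(sum((y - mean(y))^2) / (length(y) - 1)),
           n = length(y), n_dropped = d$n_dropped,
           internal_pct_accurate =
             compute_metrics(rep(mean(y), length(y)), y, cutoff_pct)$pct_accurate,
           selection_trace = tibble::tibble(step = integer(), term = character(),
                                            r2 = numeric(), delta_r2 = numeric())),
      class = "ffm_fit")
    return(fit)
  }

  fit <- fit_ols(cohort[complete.cases(cohort[term_required_fields(usable)]) &
                          !is.na(cohort$ffm_dxa_kg), ],
                 selected, cutoff_pct = cutoff_pct)
  fit$selection_trace <- dplyr::bind_rows(trace)
  fit
}

#' Refit a fixed term set within subgroups
#'
#' Checks the stability of a developed equation by refitting the same term
#' set within each level of a grouping: by sex, or by pubertal stage
#' (`tanner_early_late`, Tanner 1-2 vs 3-5). Groups too small to fit
#' (\eqn{n \le p + 2}) are skipped with a warning.
#'
#' @param fit an `ffm_fit` (its `terms` are refitted)
#' @param cohort cohort to split
#' @param grouping `"sex"` or `"tanner_early_late"`
#' @return tibble `(group, n, r2, see_kg)`
#' @export
subgroup_stability <- function(fit, cohort, grouping = c("sex", "tanner_early_late")) {
  grouping <- match.arg(grouping)
  cohort <- tibble::as_tibble(as.data.frame(cohort))
  groups <- if (grouping == "sex") {
    split(cohort, cohort$sex)
  } else {
    ok <- !is.na(cohort$tanner)
    split(cohort[ok, ], ifelse(cohort$tanner[ok] <= 2, "early", "late"))
  }
  p <- length(fit$terms)
  rows <- lapply(names(groups), function(g) {
    sub <- groups[[g]]
    n_ok <- sum(complete.cases(sub[c("ffm_dxa_kg", term_required_fields(fit$terms))]))
    if (n_ok <= p + 2L) {
      warning("subgroup '", g, "' too small (n = ", n_ok, ") for a ", p,
              "-term model; skipped", call. = FALSE)
      return(NULL)
    }
    f <- fit_ols(sub, fit$terms)
    tibble::tibble(group = g, n = f$n, r2 = f$r2, see_kg = f$see_kg)
  })
  dplyr::bind_rows(rows)
}

#' Register a fitted equation in the session registry
#'
#' Converts an `ffm_fit` into an equation spec usable by
#' [evaluate_equation()] and [predict_cohort()] alongside the built-ins.
#' The registration lasts for the R session.
#'
#' @param fit an `ffm_fit`
#' @param eq_id slug for the new equation
#' @param citation label for reports
#' @return the new `ffm_equation`, invisibly
#' @export
register_fit <- function(fit, eq_id, citation = "user-developed equation") {
  stopifnot(inherits(fit, "ffm_fit"), length(fit$terms) >= 1L)
  if (eq_id %in% equation_ids()) stop("eq_id '", eq_id, "' already registered",
                                      call. = FALSE)
  cs <- c(fit$coefficients[fit$terms], intercept = unname(fit$coefficients[["intercept"]]))
  spec <- new_equation_spec(eq_id, citation, "user cohort",
                            coefsets = list(all = cs))
  .registry$specs <- c(registry(), setNames(list(spec), eq_id))
  invisible(spec)
}
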