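#' Accuracy, bias and RMSE of predicted vs reference FFM
#'
#' Per-subject relative error is \eqn{e_i = 100\,(pred_i - dxa_i)/dxa_i}.
#' A subject is accurately predicted when \eqn{|e_i| \le} `cutoff_pct`
#' (boundary inclusive), under-predicted when \eqn{e_i < -}`cutoff_pct` and
#' over-predicted when \eqn{e_i > +}`cutoff_pct`. Bias is the mean of the
#' \eqn{e_i} (group-level accuracy); the extreme errors are the min and max
#' of \eqn{e_i}; RMSE is \eqn{\sqrt{\mathrm{mean}((pred_i - dxa_i)^2)}} in
#' kg with population denominator \eqn{n}.
#'
#' @param preds predicted FFM, kg
#' @param dxa reference (DXA) FFM, kg; all > 0
#' @param cutoff_pct accuracy cutoff in percent (default 5; 2.5 is the
#'   stricter clinically motivated alternative)
#' @param eq_id optional label carried into the result
#' @return one-row tibble: `eq_id`, `n_evaluated`, `mean_pred_kg`,
#'   `sd_pred_kg`, `pct_accurate`, `pct_under`, `pct_over`, `bias_pct`,
#'   `max_neg_err_pct`, `max_pos_err_pct`, `rmse_kg`
#' @export
compute_metrics <- function(preds, dxa, cutoff_pct = 5, eq_id = NA_character_) {
  if (length(preds) != length(dxa)) {
    stop("preds and dxa have different lengths (", length(preds), " vs ",
         length(dxa), ")", call. = FALSE)
  }
  if (length(preds) < 1L) stop("no observations", call. = FALSE)
  if (anyNA(preds) || anyNA(dxa)) stop("missing values in preds/dxa", call. = FALSE)
  if (any(dxa <= 0)) {
    stop("non-positive DXA FFM at position(s) ",
         paste(which(dxa <= 0), collapse = ", "), call. = FALSE)
  }
  stopifnot(cutoff_pct > 0)
  n <- length(preds)
  err_pct <- 100 * (preds - dxa) / dxa
  acc <- abs(err_pct) <= cutoff_pct
  under <- err_pct < -cutoff_pct
  over <- err_pct > cutoff_pct
  tibble::tibble(
    eq_id = eq_id,
    n_evaluated = n,
    mean_pred_kg = mean(preds),
    sd_pred_kg = if (n > 1) sd(preds) else 0,
    pct_accurate = 100 * mean(acc),
    pct_under = 100 * mean(under),
    pct_over = 100 * mean(over),
    bias_pct = mean(err_pct),
    max_neg_err_pct = min(err_pct),
    max_pos_err_pct = max(err_pct),
    rmse_kg = sqrt(mean((preds - dxa)^2))
  )
}

#' Validate prediction equations against DXA over a cohort
#'
#' Applies each equation to every subject with the required predictors and a
#' DXA reference value, computes [compute_metrics()] overall and within each
#' sex, and ranks the equations. The overall table is sorted by percentage
#' accurate predictions (descending), ties broken by lower RMSE.
#'
#' @param cohort a cohort with `ffm_dxa_kg` for the evaluated subjects
#' @param eq_ids equations to evaluate (default: whole registry)
#' @param cutoff_pct accuracy cutoff in percent
#' @return object of class `bia_validation`: list with `overall` and
#'   `by_sex` metric tibbles, `best_eq_id`, `ranking_trace`, `cutoff_pct`,
#'   `skipped` (pairs skipped for missing predictors) and `excluded_eqs`
#'   (equations evaluable on no subject).
#' @export
validate_equations <- function(cohort, eq_ids = equation_ids(), cutoff_pct = 5) {
  cohort <- tibble::as_tibble(as.data.frame(cohort))
  has_dxa <- !is.na(cohort$ffm_dxa_kg)
  if (!any(has_dxa)) stop("no subject has a DXA FFM value", call. = FALSE)
  eval_cohort <- cohort[has_dxa, , drop = FALSE]

  preds <- predict_cohort(eval_cohort, eq_ids)
  dxa_lookup <- setNames(eval_cohort$ffm_dxa_kg, eval_cohort$id)
  sex_lookup <- setNames(eval_cohort$sex, eval_cohort$id)

  evaluated <- unique(preds$eq_id)
  excluded <- setdiff(eq_ids, evaluated)

  one_eq <- function(eid, ids, pk, label) {
    compute_metrics(pk, dxa_lookup[ids], cutoff_pct, eq_id = eid)
  }
  overall <- dplyr::bind_rows(lapply(evaluated, function(eid) {
    p <- preds[preds$eq_id == eid, ]
    one_eq(eid, p$subject_id, p$ffm_pred_kg)
  }))
  by_sex <- dplyr::bind_rows(lapply(evaluated, function(eid) {
    p <- preds[preds$eq_id == eid, ]
    sx <- sex_lookup[p$subject_id]
    dplyr::bind_rows(lapply(c("female", "male"), function(s) {
      if (!any(sx == s)) return(NULL)
      m <- one_eq(eid, p$subject_id[sx == s], p$ffm_pred_kg[sx == s])
      dplyr::mutate(m, sex = s, .after = "eq_id")
    }))
  }))

  ord <- order(-overall$pct_accurate, overall$rmse_kg)
  overall <- overall[ord, , drop = FALSE]

  report <- structure(
    list(overall = overall, by_sex = by_sex, cutoff_pct = cutoff_pct,
         skipped = attr(preds, "skipped"), excluded_eqs = excluded,
         n_subjects = nrow(eval_cohort)),
    class = "bia_validation")
  ranked <- rank_equations(report)
  report$best_eq_id <- ranked$best_eq_id
  report$ranking_trace <- ranked$trace
  report
}

#' Select the best equation by the lexicographic ranking rule
#'
#' Criteria, applied in order with tie windows: (1) highest percentage of
#' accurate predictions (tie: within `tie_accuracy` points of the best);
#' (2) smallest absolute girl-boy gap in accurate predictions, i.e. the best
#' fit for both sexes (tie: within `tie_accuracy` points); (3) smallest
#' absolute bias (tie: within `tie_bias` points); (4) smallest RMSE. A full
#' decision trace is returned. Ties surviving all four criteria resolve to
#' the first candidate in the (stable) overall ordering.
#'
#' @param report a `bia_validation` (or a list with `overall` and `by_sex`)
#' @param tie_accuracy accuracy tie window, percentage points
#' @param tie_bias bias tie window, percentage points
#' @return list with `best_eq_id` and `trace`, a tibble of
#'   `(criterion, candidates_in, candidates_out, detail)`
#' @export
rank_equations <- function(report, tie_accuracy = 2, tie_bias = 0.5) {
  overall <- report$overall
  by_sex <- report$by_sex
  if (is.null(overall) || nrow(overall) == 0L) stop("empty report", call. = FALSE)

  cand <- overall$eq_id
  trace <- list()
  note <- function(criterion, before, after, detail) {
    trace[[length(trace) + 1L]] <<- tibble::tibble(
      criterion = criterion,
      candidates_in = paste(before, collapse = ","),
      candidates_out = paste(after, collapse = ","),
      detail = detail)
  }

  # (1) accuracy
  acc <- setNames(overall$pct_accurate, overall$eq_id)
  keep <- cand[acc[cand] >= max(acc[cand]) - tie_accuracy]
  note("pct_accurate", cand, keep,
       sprintf("best %.1f%%, tie window %g points", max(acc[cand]), tie_accuracy))
  cand <- keep

  # (2) girl-boy accuracy gap
  if (length(cand) > 1L && !is.null(by_sex) && nrow(by_sex) > 0L) {
    gap <- vapply(cand, function(eid) {
      b <- by_sex[by_sex$eq_id == eid, ]
      g <- b$pct_accurate[b$sex == "female"]
      m <- b$pct_accurate[b$sex == "male"]
      if (length(g) != 1L || length(m) != 1L) return(NA_real_)
      abs(g - m)
    }, numeric(1))
    if (!anyNA(gap)) {
      keep <- cand[gap <= min(gap) + tie_accuracy]
      note("sex_gap", cand, keep,
           sprintf("smallest gap %.1f points, tie window %g", min(gap), tie_accuracy))
      cand <- keep
    }
  }

  # (3) absolute bias
  if (length(cand) > 1L) {
    bias <- abs(setNames(overall$bias_pct, overall$eq_id)[cand])
    keep <- cand[bias <= min(bias) + tie_bias]
    note("abs_bias", cand, keep,
         sprintf("smallest |bias| %.2f%%, tie window %g", min(bias), tie_bias))
    cand <- keep
  }

  # (4) RMSE
  if (length(cand) > 1L) {
    rmse <- setNames(overall$rmse_kg, overall$eq_id)[cand]
    keep <- cand[rmse == min(rmse)]
    note("rmse", cand, keep, sprintf("smallest RMSE %.2f kg", min(rmse)))
    cand <- keep
  }

  list(best_eq_id = cand[[1L]], trace = dplyr::bind_rows(trace))
}

#' @export
print.bia_validation <- function(x, ...) {
  cat("<bia_validation> ", nrow(x$overall), " equations on ", x$n_subjects,
      " subjects, cutoff ±", x$cutoff_pct, "%\n", sep = "")
  cat("best equation: ", x$best_eq_id, "\n\n", sep = "")
  print(format_metrics_table(x$overall))
  invisible(x)
}

# Table-3-style rendering: percentages and kg to 1 decimal
format_metrics_table <- function(m) {
  out <- m
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "n_evaluated"
  out[num] <- lapply(out[num], round, 1)
  out
}

#' Agreement of predicted vs DXA change over follow-up
#'
#' Matches subjects by id between a baseline and a follow-up cohort,
#' computes each subject's DXA FFM change and predicted FFM change under one
#' equation, and tests the paired differences (predicted change minus DXA
#' change) with a two-sided paired t-test.
#'
#' @param baseline,followup cohorts with matching subject ids and DXA values
#' @param eq_id equation to evaluate
#' @return one-row tibble: `eq_id`, `n_pairs`, `mean_change_dxa_kg`,
#'   `sd_change_dxa_kg`, `mean_change_pred_kg`, `mean_diff_kg`, `sd_diff_kg`,
#'   `p_value`. With zero variance in the differences the t-test is
#'   undefined: `p_value` is `NA` and `degenerate` is `TRUE`.
#' @export
evaluate_change <- function(baseline, followup, eq_id) {
  baseline <- tibble::as_tibble(as.data.frame(baseline))
  followup <- tibble::as_tibble(as.data.frame(followup))
  ids <- intersect(baseline$id, followup$id)
  if (length(ids) == 0L) stop("no matched subject ids", call. = FALSE)
  b <- baseline[match(ids, baseline$id), ]
  f <- followup[match(ids, followup$id), ]
  ok <- !is.na(b$ffm_dxa_kg) & !is.na(f$ffm_dxa_kg)
  b <- b[ok, ]; f <- f[ok, ]
  if (nrow(b) < 2L) stop("need at least 2 matched pairs with DXA values",
                         call. = FALSE)

  d_dxa <- f$ffm_dxa_kg - b$ffm_dxa_kg
  d_pred <- evaluate_equation(eq_id, f) - evaluate_equation(eq_id, b)
  diffs <- d_pred - d_dxa

  degenerate <- sd(diffs) == 0
  p <- if (degenerate) NA_real_ else t.test(diffs)$p.value
  tibble::tibble(
    eq_id = eq_id, n_pairs = length(diffs),
    mean_change_dxa_kg = mean(d_dxa), sd_change_dxa_kg = sd(d_dxa),
    mean_change_pred_kg = mean(d_pred),
    mean_diff_kg = mean(diffs), sd_diff_kg = sd(diffs),
    p_value = p, degenerate = degenerate)
}
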