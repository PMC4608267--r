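test_that("worked four-subject example: classification, bias, extremes, RMSE", {
  m <- compute_metrics(c(50, 52, 47, 56), c(50, 50, 50, 50))
  expect_equal(m$pct_accurate, 50)
  expect_equal(m$pct_under, 25)
  expect_equal(m$pct_over, 25)
  expect_equal(m$bias_pct, 2.5)
  expect_equal(m$max_neg_err_pct, -6)
  expect_equal(m$max_pos_err_pct, 12)
  expect_equal(m$rmse_kg, 3.5)
})

test_that("degenerate inputs: identity and constant offset", {
  m <- compute_metrics(c(44.2, 61.8, 50), c(44.2, 61.8, 50))
  expect_equal(m$pct_accurate, 100)
  expect_equal(m$bias_pct, 0)
  expect_equal(m$rmse_kg, 0)
  expect_equal(compute_metrics(c(42, 82), c(40, 80))$rmse_kg, 2)
})

test_that("input contracts: length mismatch and non-positive reference", {
  expect_error(compute_metrics(1:3, 1:2), "different lengths")
  expect_error(compute_metrics(c(50, 50), c(50, -1)), "position\\(s\\) 2")
})

test_that("accuracy boundary at exactly the cutoff is inclusive", {
  m <- compute_metrics(c(52.5, 47.5, 52.50001), c(50, 50, 50))
  expect_equal(m$pct_accurate, 2 / 3 * 100)
  expect_equal(m$pct_over, 1 / 3 * 100)
})

test_that("metrics equal brute-force per-element recomputation on small cohorts", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(1:6, 1)
    dxa <- runif(n, 40, 80)
    preds <- dxa * runif(n, 0.85, 1.15)
    cutoff <- sample(c(2.5, 5, 10), 1)
    m <- compute_metrics(preds, dxa, cutoff)
    # independent element-wise recomputation
    e <- numeric(n); acc <- und <- ovr <- 0; ss <- 0
    for (i in seq_len(n)) {
      e[i] <- 100 * (preds[i] - dxa[i]) / dxa[i]
      if (e[i] < -cutoff) und <- und + 1
      else if (e[i] > cutoff) ovr <- ovr + 1
      else acc <- acc + 1
      ss <- ss + (preds[i] - dxa[i])^2
    }
    expect_equal(m$pct_accurate, 100 * acc / n)
    expect_equal(m$pct_under, 100 * und / n)
    expect_equal(m$pct_over, 100 * ovr / n)
    expect_equal(m$bias_pct, sum(e) / n)
    expect_equal(m$max_neg_err_pct, min(e))
    expect_equal(m$max_pos_err_pct, max(e))
    expect_equal(m$rmse_kg, sqrt(ss / n))
  }
})

test_that("classification partitions subjects and accuracy grows with the cutoff", {
  set.seed(7)
  dxa <- runif(40, 40, 80)
  preds <- dxa * runif(40, 0.8, 1.2)
  prev <- -1
  for (cutoff in c(1, 2.5, 5, 10, 25)) {
    m <- compute_metrics(preds, dxa, cutoff)
    expect_equal(m$pct_accurate + m$pct_under + m$pct_over, 100)
    expect_gte(m$pct_accurate, prev)
    prev <- m$pct_accurate
  }
})

test_that("RMSE dominates the absolute mean kg error, equality for constant errors", {
  set.seed(8)
  dxa <- runif(30, 40, 80)
  preds <- dxa + rnorm(30, 1, 2)
  m <- compute_metrics(preds, dxa)
  expect_gte(m$rmse_kg, abs(mean(preds - dxa)))
  m2 <- compute_metrics(dxa - 1.3, dxa)
  expect_equal(m2$rmse_kg, abs(mean(-1.3)), tolerance = 1e-12)
})

test_that("sex-stratified accurate counts reweight to the overall percentage", {
  co <- random_cohort(24, seed = 3)
  v <- validate_equations(co, c("gray", "haroun", "new_hofsteenge"))
  for (eid in v$overall$eq_id) {
    o <- v$overall[v$overall$eq_id == eid, ]
    b <- v$by_sex[v$by_sex$eq_id == eid, ]
    expect_equal(sum(b$n_evaluated * b$pct_accurate) / sum(b$n_evaluated),
                 o$pct_accurate, tolerance = 1e-9, label = eid)
  }
})

test_that("an equation reproducing DXA exactly ranks first at 100% accuracy", {
  co <- random_cohort(12, seed = 5)
  co$ffm_dxa_kg <- evaluate_equation("haroun", co)
  v <- validate_equations(co, c("haroun", "gray", "suprasongsin"))
  expect_equal(v$overall$eq_id[1], "haroun")
  expect_equal(v$overall$pct_accurate[1], 100)
  expect_equal(v$best_eq_id, "haroun")
})

test_that("overall table sorts by accuracy, RMSE breaking ties", {
  co <- random_cohort(15, seed = 9)
  v <- validate_equations(co)
  acc <- v$overall$pct_accurate
  expect_true(all(diff(acc) <= 0))
  ties <- which(diff(acc) == 0)
  for (i in ties) expect_lte(v$overall$rmse_kg[i], v$overall$rmse_kg[i + 1])
})

test_that("equation evaluable on no subject is excluded but reported", {
  co <- dplyr::bind_rows(mean_subject(id = "a"), mean_subject(id = "b", sex = "F"))
  co$reactance_ohm <- NA_real_
  co <- suppressWarnings(as_bia_cohort(co))
  v <- validate_equations(co, c("kyle", "haroun"))
  expect_false("kyle" %in% v$overall$eq_id)
  expect_true("kyle" %in% v$excluded_eqs)
})

test_that("ranking applies the four criteria lexicographically", {
  mk <- function(eq, acc, bias, rmse, acc_f, acc_m) {
    overall <- tibble::tibble(eq_id = eq, n_evaluated = 100,
      mean_pred_kg = 56, sd_pred_kg = 9, pct_accurate = acc,
      pct_under = 0, pct_over = 0, bias_pct = bias,
      max_neg_err_pct = -10, max_pos_err_pct = 10, rmse_kg = rmse)
    by_sex <- dplyr::bind_rows(
      tibble::tibble(eq_id = eq, sex = "female", n_evaluated = 60,
                     mean_pred_kg = 56, sd_pred_kg = 9, pct_accurate = acc_f,
                     pct_under = 0, pct_over = 0, bias_pct = bias,
                     max_neg_err_pct = -10, max_pos_err_pct = 10, rmse_kg = rmse),
      tibble::tibble(eq_id = eq, sex = "male", n_evaluated = 40,
                     mean_pred_kg = 56, sd_pred_kg = 9, pct_accurate = acc_m,
                     pct_under = 0, pct_over = 0, bias_pct = bias,
                     max_neg_err_pct = -10, max_pos_err_pct = 10, rmse_kg = rmse))
    list(overall = overall, by_sex = by_sex)
  }

  # criterion 1 decides: accuracies 68/63/61, all beyond the 2-point window
  r <- rank_equations(mk(c("a", "b", "c"), acc = c(68, 63, 61),
                         bias = c(2, 1, 0.5), rmse = c(3, 3, 3),
                         acc_f = c(68, 63, 61), acc_m = c(68, 63, 61)))
  expect_equal(r$best_eq_id, "a")
  expect_equal(r$trace$criterion[1], "pct_accurate")

  # criterion 2 decides: equal accuracy, sex gaps 1 vs 20 points
  r2 <- rank_equations(mk(c("a", "b"), acc = c(65, 65), bias = c(1, 1),
                          rmse = c(3, 3), acc_f = c(65.5, 75), acc_m = c(64.5, 55)))
  expect_equal(r2$best_eq_id, "a")
  expect_true("sex_gap" %in% r2$trace$criterion)

  # criterion 3 then 4
  r3 <- rank_equations(mk(c("a", "b"), acc = c(65, 65), bias = c(0.1, 3),
                          rmse = c(4, 3), acc_f = c(65, 65), acc_m = c(65, 65)))
  expect_equal(r3$best_eq_id, "a")
  r4 <- rank_equations(mk(c("a", "b"), acc = c(65, 65), bias = c(0.1, 0.3),
                          rmse = c(4, 3), acc_f = c(65, 65), acc_m = c(65, 65)))
  expect_equal(r4$best_eq_id, "b")

  # singleton
  r5 <- rank_equations(mk("only", 50, 1, 3, 50, 50))
  expect_equal(r5$best_eq_id, "only")
  expect_equal(nrow(r5$trace), 1L)
  expect_error(rank_equations(list(overall = NULL)), "empty report")
})

test_that("change agreement recovers hand-computable paired statistics", {
  base <- random_cohort(4, seed = 21)
  fol <- base
  # follow-up constructed so predicted change == DXA change exactly
  fol$ffm_dxa_kg <- base$ffm_dxa_kg + 2
  fol$impedance_ohm <- base$height_cm^2 /
    (base$height_cm^2 / base$impedance_ohm + 2 / 1.115)
  fol$resistance_ohm <- sqrt(fol$impedance_ohm^2 - fol$reactance_ohm^2)
  ca <- evaluate_change(base, as_bia_cohort(fol), "haroun")
  expect_equal(ca$mean_change_dxa_kg, 2)
  expect_equal(ca$mean_diff_kg, 0, tolerance = 1e-9)
  expect_true(ca$degenerate || ca$p_value > 0.9999)

  # diffs +1/-1: mean 0, sd sqrt(2)
  fol2 <- fol[1:2, ]
  fol2$ffm_dxa_kg <- fol2$ffm_dxa_kg + c(-1, 1)  # pred change - dxa change = +1, -1
  ca2 <- evaluate_change(base[1:2, ], as_bia_cohort(fol2), "haroun")
  expect_equal(ca2$mean_diff_kg, 0, tolerance = 1e-9)
  expect_equal(ca2$sd_diff_kg, sqrt(2), tolerance = 1e-9)

  # near-constant nonzero diffs: closed-form t at n=4 explodes
  fol3 <- fol
  fol3$ffm_dxa_kg <- fol3$ffm_dxa_kg - 2 + c(1e-12, -1e-12, 1e-12, -1e-12)
  ca3 <- evaluate_change(base, as_bia_cohort(fol3), "haroun")
  expect_lt(ca3$p_value, 1e-6)

  expect_error(evaluate_change(base, within(as.data.frame(fol), id <- paste0("x", id)),
                               "haroun"), "no matched")
})
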