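# Frozen expected values computed beforehand with an independent calculator
# from the published formulas, at the mean subject (H 166 cm, W 94.3 kg,
# age 14.4 y, R 505.2, Xc 62.6, Z 509.1 ohm).
FROZEN_MALE <- c(
  deurenberg91 = 59.266318, deurenberg90 = 57.721394, houtkooper = 58.157288,
  kyle = 58.300473, suprasongsin = 67.395941, gray = 55.300420,
  lukaski = 52.844019, schaefer = 45.124479, sun = 59.396078,
  haroun = 58.140483, horie = 62.210000, lazzer = 50.190395,
  wabitsch = 49.263193, new_hofsteenge = 55.518671)
FROZEN_FEMALE_DIFFER <- c(
  deurenberg91 = 58.706318, deurenberg90 = 56.121394, kyle = 54.071473,
  gray = 55.544480, sun = 54.240867)

test_that("registry holds the 13 literature equations plus the new one", {
  specs <- list_equations()
  expect_length(specs, 14L)
  expect_equal(sum(names(specs) != "new_hofsteenge"), 13L)
  expect_identical(ffm_equation("gray")$sex_handling, "sex_specific")
  expect_identical(ffm_equation("deurenberg91")$age_cut, 16)
  expect_error(ffm_equation("nonexistent"), "unknown equation id")
})

test_that("every equation reproduces its hand-computed value at the mean subject", {
  male <- mean_cohort(sex = "M")
  female <- mean_cohort(sex = "F")
  for (eid in names(FROZEN_MALE)) {
    expect_equal(evaluate_equation(eid, male), FROZEN_MALE[[eid]],
                 tolerance = 1e-6, label = paste(eid, "(male)"))
  }
  for (eid in names(FROZEN_FEMALE_DIFFER)) {
    expect_equal(evaluate_equation(eid, female), FROZEN_FEMALE_DIFFER[[eid]],
                 tolerance = 1e-6, label = paste(eid, "(female)"))
  }
  # unisex equations are sex-invariant
  unisex <- setdiff(names(FROZEN_MALE),
                    c(names(FROZEN_FEMALE_DIFFER)))
  for (eid in unisex) {
    expect_equal(evaluate_equation(eid, female), FROZEN_MALE[[eid]],
                 tolerance = 1e-6, label = paste(eid, "sex-invariant"))
  }
})

test_that("sex offset of the 1990 Deurenberg equation is exactly its SEX coefficient", {
  d <- evaluate_equation("deurenberg90", mean_cohort(sex = "M")) -
    evaluate_equation("deurenberg90", mean_cohort(sex = "F"))
  expect_equal(d, 1.6, tolerance = 1e-12)
})

test_that("age branching of the 1991 Deurenberg equation switches at 16 y", {
  young <- evaluate_equation("deurenberg91", mean_cohort(age = 15.99))
  old <- evaluate_equation("deurenberg91", mean_cohort(age = 16.0))
  # independent hand evaluation of each branch at those ages
  zi <- 166^2 / 509.1
  expect_equal(young, 0.406 * zi + 0.360 * 94.3 + 0.0558 * 166 + 0.56 - 6.48,
               tolerance = 1e-9)
  expect_equal(old, 0.340 * zi + 0.1534 * 166 + 0.273 * 94.3 - 0.127 * 16 +
                 4.56 - 12.44, tolerance = 1e-9)
})

test_that("the Horie fat-mass form makes the prediction weight-independent", {
  heavy <- mean_subject(); heavy$weight_kg <- 120
  light <- mean_subject(); light$weight_kg <- 60
  expect_equal(evaluate_equation("horie", as_bia_cohort(heavy)),
               evaluate_equation("horie", as_bia_cohort(light)),
               tolerance = 1e-9)
})

test_that("missing predictors and unknown sex raise named errors", {
  s <- mean_subject()
  s$reactance_ohm <- NA_real_
  expect_error(evaluate_equation("kyle", s), "reactance_ohm")
  s2 <- mean_subject(tanner = NA)
  s2$age <- NA_real_
  expect_error(evaluate_equation("deurenberg91", s2), "age")
})

test_that("implausible predictions are returned unclipped with a warning", {
  tiny <- mean_subject()
  tiny$height_cm <- 30; tiny$impedance_ohm <- 2000; tiny$resistance_ohm <- 1999
  expect_warning(v <- evaluate_equation("haroun", as_bia_cohort(tiny)),
                 "implausible")
  expect_lt(v, 0)
})

test_that("predict_cohort yields one prediction per evaluable pair and logs skips", {
  co <- as_bia_cohort(dplyr::bind_rows(mean_subject(id = "a"),
                                       mean_subject(id = "b", sex = "F")))
  out <- predict_cohort(co, c("gray", "haroun", "lazzer"))
  expect_equal(nrow(out), 6L)

  co2 <- dplyr::bind_rows(mean_subject(id = "a"), mean_subject(id = "b"))
  co2$reactance_ohm[2] <- NA_real_
  co2 <- suppressWarnings(as_bia_cohort(co2))
  out2 <- predict_cohort(co2, c("kyle", "haroun"))
  expect_equal(nrow(out2), 3L)  # kyle skips subject b
  sk <- attr(out2, "skipped")
  expect_equal(sk$eq_id, "kyle")
  expect_equal(sk$subject_id, "b")
  expect_equal(sk$missing_field, "reactance_ohm")
  expect_error(predict_cohort(co[0, ]), "empty")
})

test_that("new equation matches hand arithmetic on the index", {
  expect_equal(evaluate_equation("new_hofsteenge", mean_cohort()),
               0.527 * (166^2 / 509.1) + 0.306 * 94.3 - 1.862,
               tolerance = 1e-12)
})

test_that("equations are linear in their registered terms", {
  # evaluating at a convex combination of two predictor vectors equals the
  # combination of the evaluations (composite indices treated as the predictor)
  co <- random_cohort(6, seed = 11)
  for (eid in c("houtkooper", "haroun", "kyle", "new_hofsteenge")) {
    eq <- ffm_equation(eid)
    t1 <- build_terms(co[1, ], eq$terms)
    t2 <- build_terms(co[2, ], eq$terms)
    w <- 0.3
    blend <- co[1, ]
    # construct a subject whose terms are the blend; invert composite tags
    mix <- w * t1 + (1 - w) * t2
    blend$weight_kg <- if ("W" %in% eq$terms) mix$W else blend$weight_kg
    blend$reactance_ohm <- if ("X" %in% eq$terms) mix$X else blend$reactance_ohm
    if ("H2_over_R" %in% eq$terms) {
      blend$resistance_ohm <- blend$height_cm^2 / mix$H2_over_R
    }
    if ("H2_over_Z" %in% eq$terms) {
      blend$impedance_ohm <- blend$height_cm^2 / mix$H2_over_Z
    }
    if ("SEX01" %in% eq$terms) next  # sex is not blendable
    v <- evaluate_equation(eq, blend)
    expect_equal(v, w * evaluate_equation(eq, co[1, ]) +
                   (1 - w) * evaluate_equation(eq, co[2, ]),
                 tolerance = 1e-9, label = paste(eid, "linearity"))
  }
})

test_that("every registered predictor tag resolves from subject fields", {
  co <- mean_cohort()
  for (eq in list_equations()) {
    terms <- build_terms(co, eq$terms)
    expect_true(all(vapply(terms, is.finite, logical(1))),
                label = paste(eq$eq_id, "terms resolvable"))
  }
})

test_that("registry JSON export round-trips ids and coefficients", {
  js <- jsonlite::fromJSON(export_registry(), simplifyVector = FALSE)
  expect_length(js, 14L)
  expect_equal(js$gray$coefficients$male$H2, 0.00139)
  expect_equal(js$wabitsch$postscale, 0.732)
})
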