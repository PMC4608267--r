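# Calibration constants for the impedance index ZI = H(cm)^2/Z.
# The study tables print moments for height, weight, resistance, reactance,
# impedance and DXA FFM, but not for ZI nor its correlation with weight.
# These two constants are derived by moment matching so that the generative
# linear model FFM = 0.527*ZI + 0.306*W - 1.862 + N(0, 2.85) reproduces the
# printed FFM moments (mean 56.1, sd 9.8 kg) and explained variances
# (single-predictor R2 0.82, two-predictor R2 0.92):
#   Var(FFM) = .527^2 s_ZI^2 + .306^2 s_W^2 + 2(.527)(.306) rho s_ZI s_W + 2.85^2
# With s_W = 15.7, s_ZI = 9.74 and rho = 0.78 this gives Var(FFM) = 96.02
# (sd 9.80), R2(ZI) = 0.821, R2(ZI, W) = 0.915, mean FFM
# 0.527*55.2 + 0.306*94.3 - 1.862 = 56.08. See cohort_calibration().
ZI_MEAN <- 55.2
ZI_SD <- 9.74
ZI_WEIGHT_CORR <- 0.78

#' Generative parameters of the synthetic obese-adolescent cohort
#'
#' Defaults are the study conditions: n = 103 with 61 girls, age 14.4 (1.7) y
#' truncated to 11-18, sex-specific heights (girls 164.0 (6.0), boys 169.0
#' (12.0) cm), weight 94.3 (15.7) kg truncated above 40 kg and correlated
#' 0.5 with height, reactance 62.6 (7.7) ohm, and the impedance index
#' ZI = H^2/Z conditionally normal given weight with the moment-matched
#' calibration constants (mean 55.2, sd 9.74 cm^2/ohm, correlation 0.78 with
#' weight). DXA FFM follows the generative linear model
#' FFM = 0.527 ZI + 0.306 W - 1.862 + N(0, 2.85 kg). Follow-up FFM change is
#' N(1.49, 2.72) kg over six months.
#'
#' @param n cohort size
#' @param p_female probability a subject is a girl
#' @param age_mean,age_sd,age_range age distribution, years (truncated)
#' @param height_female,height_male `c(mean, sd)` height by sex, cm
#' @param weight_mean,weight_sd,weight_min weight distribution, kg (truncated)
#' @param corr_weight_height height-weight correlation within sex
#' @param zi_mean,zi_sd moments of ZI = H^2/Z, cm^2/ohm (calibration constants)
#' @param corr_zi_weight ZI-weight correlation (calibration constant)
#' @param ffm_coefs generative coefficients `c(zi, weight, intercept)`
#' @param resid_sd_kg residual sd of the generative FFM model, kg
#' @param reactance_mean,reactance_sd reactance distribution, ohm
#' @param followup_mean,followup_sd six-month DXA FFM change, kg
#' @param tanner_age_cut,tanner_flip_prob pubertal-stage assignment: stage 1
#'   if age < cut, flipped with the given probability
#' @return list of class `cohort_params`
#' @export
cohort_params <- function(n = 103,
                          p_female = 61 / 103,
                          age_mean = 14.4, age_sd = 1.7, age_range = c(11, 18),
                          height_female = c(164.0, 6.0),
                          height_male = c(169.0, 12.0),
                          weight_mean = 94.3, weight_sd = 15.7, weight_min = 40,
                          corr_weight_height = 0.5,
                          zi_mean = ZI_MEAN, zi_sd = ZI_SD,
                          corr_zi_weight = ZI_WEIGHT_CORR,
                          ffm_coefs = c(zi = 0.527, weight = 0.306,
                                        intercept = -1.862),
                          resid_sd_kg = 2.85,
                          reactance_mean = 62.6, reactance_sd = 7.7,
                          followup_mean = 1.49, followup_sd = 2.72,
                          tanner_age_cut = 12.5, tanner_flip_prob = 0.15) {
  p <- as.list(environment())
  stopifnot(p$n >= 1, p$p_female >= 0, p$p_female <= 1,
            p$age_sd > 0, p$weight_sd > 0, p$zi_sd > 0,
            p$reactance_sd > 0, p$resid_sd_kg >= 0,
            abs(p$corr_weight_height) < 1, abs(p$corr_zi_weight) < 1)
  structure(p, class = "cohort_params")
}

# rejection-sampled truncated normal; cap guards against unsatisfiable bounds
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf, max_tries = 1000L) {
  x <- rnorm(n, mean, sd)
  bad <- x < lower | x > upper
  tries <- 0L
  while (any(bad)) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("truncation bounds unsatisfied after ", max_tries,
           " resampling rounds", call. = FALSE)
    }
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lower | x > upper
  }
  x
}

#' Generate a synthetic cohort
#'
#' Draws subjects from the generative model in [cohort_params()]: sex is
#' Bernoulli, height and weight are bivariate normal within sex, the
#' impedance index ZI is conditionally normal given weight, DXA FFM follows
#' the generative linear model, and the BIA fields are derived physically:
#' impedance Z = H^2/ZI, reactance drawn, resistance
#' R = sqrt(Z^2 - Xc^2). Subjects violating Z > Xc are resampled (reactance
#' first) with a 1000-round cap. Fully reproducible for a given seed.
#'
#' @param params a `cohort_params`
#' @param seed integer seed
#' @return a `bia_cohort` with attribute `params`; the latent impedance
#'   index is carried in attribute `zi` (it also equals `height_cm^2 /
#'   impedance_ohm` exactly)
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1L) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(as.integer(seed))
  n <- params$n

  sex <- ifelse(runif(n) < params$p_female, "female", "male")
  age <- rnorm_trunc(n, params$age_mean, params$age_sd,
                     params$age_range[1], params$age_range[2])

  hmu <- ifelse(sex == "female", params$height_female[1], params$height_male[1])
  hsd <- ifelse(sex == "female", params$height_female[2], params$height_male[2])
  height <- rnorm(n, hmu, hsd)
  # weight | height: conditional normal with the stated correlation,
  # truncated below weight_min by rejection
  wmu <- params$weight_mean +
    params$corr_weight_height * params$weight_sd * (height - hmu) / hsd
  wsd <- params$weight_sd * sqrt(1 - params$corr_weight_height^2)
  weight <- rnorm(n, wmu, wsd)
  bad <- weight <= params$weight_min
  tries <- 0L
  while (any(bad)) {
    tries <- tries + 1L
    if (tries > 1000L) stop("weight truncation unsatisfied", call. = FALSE)
    weight[bad] <- rnorm(sum(bad), wmu[bad], wsd)
    bad <- weight <= params$weight_min
  }

  # ZI | weight
  zmu <- params$zi_mean + params$corr_zi_weight * params$zi_sd *
    (weight - params$weight_mean) / params$weight_sd
  zsd <- params$zi_sd * sqrt(1 - params$corr_zi_weight^2)
  zi <- rnorm(n, zmu, zsd)
  bad <- zi <= 0
  tries <- 0L
  while (any(bad)) {  # ZI must be positive for Z = H^2/ZI
    tries <- tries + 1L
    if (tries > 1000L) stop("could not draw positive impedance index", call. = FALSE)
    zi[bad] <- rnorm(sum(bad), zmu[bad], zsd)
    bad <- zi <= 0
  }

  ffm <- params$ffm_coefs[["zi"]] * zi + params$ffm_coefs[["weight"]] * weight +
    params$ffm_coefs[["intercept"]] + rnorm(n, 0, params$resid_sd_kg)

  impedance <- height^2 / zi
  reactance <- rnorm(n, params$reactance_mean, params$reactance_sd)
  bad <- reactance < 0 | reactance >= impedance
  tries <- 0L
  n_resampled <- sum(bad)
  while (any(bad)) {
    tries <- tries + 1L
    if (tries > 1000L) {
      stop("impedance/reactance constraint unsatisfied after 1000 rounds",
           call. = FALSE)
    }
    reactance[bad] <- rnorm(sum(bad), params$reactance_mean, params$reactance_sd)
    bad <- reactance < 0 | reactance >= impedance
  }
  resistance <- sqrt(impedance^2 - reactance^2)

  stage1 <- (age < params$tanner_age_cut)
  flip <- runif(n) < params$tanner_flip_prob
  stage1 <- xor(stage1, flip)
  tanner <- ifelse(stage1, 1L, sample(2:5, n, replace = TRUE))

  cohort <- as_bia_cohort(tibble::tibble(
    id = sprintf("S%04d", seq_len(n)), sex = ifelse(sex == "female", "F", "M"),
    age = age, height_cm = height, weight_kg = weight,
    resistance_ohm = resistance, reactance_ohm = reactance,
    impedance_ohm = impedance, tanner = tanner, ffm_dxa_kg = ffm,
    bmi_sds = NA_real_))
  attr(cohort, "params") <- params
  attr(cohort, "zi") <- zi
  attr(cohort, "n_resampled") <- n_resampled
  cohort
}

#' Generate a six-month follow-up for a synthetic baseline cohort
#'
#' Per subject, the DXA FFM change is drawn N(`followup_mean`,
#' `followup_sd`); body weight changes by the FFM change plus an independent
#' fat-mass change N(0, 2) kg. The impedance index is re-derived by
#' inverting the generative FFM model at the new FFM with a fresh residual,
#' and the BIA fields (Z, Xc, R) are recomputed from it.
#'
#' @param baseline a cohort produced by [generate_cohort()] (the stored
#'   latent impedance index is required)
#' @param seed integer seed
#' @param fm_change_sd sd of the independent fat-mass change, kg
#' @return a `bia_cohort` of the same subjects at follow-up
#' @export
generate_followup <- function(baseline, seed = 2L, fm_change_sd = 2.0) {
  params <- attr(baseline, "params")
  if (is.null(params) || is.null(attr(baseline, "zi"))) {
    stop("baseline was not produced by generate_cohort() ",
         "(latent impedance index not stored)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- nrow(baseline)
  d_ffm <- rnorm(n, params$followup_mean, params$followup_sd)
  d_fm <- rnorm(n, 0, fm_change_sd)

  ffm2 <- baseline$ffm_dxa_kg + d_ffm
  weight2 <- pmax(baseline$weight_kg + d_ffm + d_fm, params$weight_min)
  resid2 <- rnorm(n, 0, params$resid_sd_kg)
  zi2 <- (ffm2 - params$ffm_coefs[["weight"]] * weight2 -
            params$ffm_coefs[["intercept"]] - resid2) / params$ffm_coefs[["zi"]]
  if (any(zi2 <= 0)) stop("follow-up impedance index non-positive", call. = FALSE)

  impedance2 <- baseline$height_cm^2 / zi2
  reactance2 <- rnorm(n, params$reactance_mean, params$reactance_sd)
  bad <- reactance2 < 0 | reactance2 >= impedance2
  tries <- 0L
  while (any(bad)) {
    tries <- tries + 1L
    if (tries > 1000L) stop("impedance/reactance constraint unsatisfied", call. = FALSE)
    reactance2[bad] <- rnorm(sum(bad), params$reactance_mean, params$reactance_sd)
    bad <- reactance2 < 0 | reactance2 >= impedance2
  }

  # subjects near the upper age bound legitimately age past it by follow-up
  quiet_age <- function(expr) withCallingHandlers(expr,
    warning = function(w) if (grepl("age window", conditionMessage(w)))
      invokeRestart("muffleWarning"))
  followup <- quiet_age(as_bia_cohort(tibble::tibble(
    id = baseline$id, sex = ifelse(baseline$sex == "female", "F", "M"),
    age = baseline$age + 0.5, height_cm = baseline$height_cm,
    weight_kg = weight2, resistance_ohm = sqrt(impedance2^2 - reactance2^2),
    reactance_ohm = reactance2, impedance_ohm = impedance2,
    tanner = baseline$tanner, ffm_dxa_kg = ffm2, bmi_sds = NA_real_)))
  attr(followup, "params") <- params
  attr(followup, "zi") <- zi2
  followup
}

#' Subject-characteristics summary
#'
#' Mean (sd) of the anthropometric, BIA and DXA variables overall and by
#' sex, plus the pre-pubertal/pubertal Tanner counts — the shape of a
#' standard cohort-description table. With a single subject (or identical
#' subjects) the sd is reported as 0 and flagged.
#'
#' @param cohort a cohort data frame
#' @return list with `stats` (tibble: variable, group, n, mean, sd),
#'   `tanner` (tibble of pre-pubertal/pubertal counts by group) and
#'   `degenerate_sd` flag
#' @export
summarize_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(as.data.frame(cohort))
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  vars <- c(age = "age", height_cm = "height_cm", weight_kg = "weight_kg",
            bmi = NA, resistance_ohm = "resistance_ohm",
            reactance_ohm = "reactance_ohm", impedance_ohm = "impedance_ohm",
            ffm_dxa_kg = "ffm_dxa_kg")
  cohort$bmi <- cohort$weight_kg / (cohort$height_cm / 100)^2

  groups <- c(list(total = cohort), split(cohort, cohort$sex))
  stats <- dplyr::bind_rows(lapply(names(groups), function(g) {
    sub <- groups[[g]]
    dplyr::bind_rows(lapply(names(vars), function(v) {
      col <- if (is.na(vars[[v]])) "bmi" else vars[[v]]
      x <- sub[[col]][!is.na(sub[[col]])]
      tibble::tibble(variable = v, group = g, n = length(x),
                     mean = if (length(x)) mean(x) else NA_real_,
                     sd = if (length(x) > 1) sd(x) else 0)
    }))
  }))
  tanner <- dplyr::bind_rows(lapply(names(groups), function(g) {
    tn <- groups[[g]]$tanner
    tibble::tibble(group = g,
                   pre_pubertal = sum(tn == 1, na.rm = TRUE),
                   pubertal = sum(tn >= 2, na.rm = TRUE),
                   missing = sum(is.na(tn)))
  }))
  degenerate <- nrow(cohort) == 1L || any(stats$sd == 0 & stats$n > 1)
  list(stats = stats, tanner = tanner, degenerate_sd = degenerate)
}

#' Implied moments of the generative model
#'
#' Closed-form variance decomposition of the generative FFM model: implied
#' FFM mean and variance, the single-predictor explained variance of FFM on
#' the impedance index, and the two-predictor explained variance. Used to
#' document (and test) the moment-matching calibration.
#'
#' @param params a `cohort_params`
#' @return list: `ffm_mean`, `ffm_var`, `ffm_sd`, `r2_zi`, `r2_zi_w`
#' @export
cohort_calibration <- function(params = cohort_params()) {
  b1 <- params$ffm_coefs[["zi"]]; b2 <- params$ffm_coefs[["weight"]]
  szi <- params$zi_sd; sw <- params$weight_sd
  rho <- params$corr_zi_weight
  cov_zw <- rho * szi * sw
  ffm_var <- b1^2 * szi^2 + b2^2 * sw^2 + 2 * b1 * b2 * cov_zw +
    params$resid_sd_kg^2
  cov_zf <- b1 * szi^2 + b2 * cov_zw
  list(
    ffm_mean = b1 * params$zi_mean + b2 * params$weight_mean +
      params$ffm_coefs[["intercept"]],
    ffm_var = ffm_var, ffm_sd = sqrt(ffm_var),
    r2_zi = cov_zf^2 / (szi^2 * ffm_var),
    r2_zi_w = 1 - params$resid_sd_kg^2 / ffm_var)
}
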