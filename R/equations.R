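# Predictor-term vocabulary. Every registered equation is a linear
# combination of these terms (heights internally in cm; formulas published
# with H in metres are stored pre-converted so a single unit convention
# holds at evaluation time).
TERM_FIELDS <- list(
  H2_over_R = c("height_cm", "resistance_ohm"),
  H2_over_Z = c("height_cm", "impedance_ohm"),
  H2        = "height_cm",
  H         = "height_cm",
  W         = "weight_kg",
  AGE       = "age",
  SEX01     = "sex",
  R         = "resistance_ohm",
  X         = "reactance_ohm",
  Z         = "impedance_ohm",
  BMI       = c("height_cm", "weight_kg"),
  TANNER2   = "tanner"
)

#' Build predictor term columns from a cohort
#'
#' Maps symbolic predictor tags onto numeric columns: `H2_over_R` and
#' `H2_over_Z` are the resistance and impedance indices (height squared in
#' cm\eqn{^2} over ohm), `SEX01` codes male = 1 / female = 0, `BMI` is
#' kg/m\eqn{^2}, and `TANNER2` is the pubertal dummy (Tanner stage \eqn{\ge} 2).
#'
#' @param cohort cohort data frame
#' @param tags character vector of term tags (see `TERM_FIELDS`)
#' @return tibble with one numeric column per tag
#' @export
build_terms <- function(cohort, tags) {
  unknown <- setdiff(tags, names(TERM_FIELDS))
  if (length(unknown)) {
    stop("unknown predictor tag(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cols <- lapply(tags, function(tag) {
    switch(tag,
      H2_over_R = cohort$height_cm^2 / cohort$resistance_ohm,
      H2_over_Z = cohort$height_cm^2 / cohort$impedance_ohm,
      H2        = cohort$height_cm^2,
      H         = cohort$height_cm,
      W         = cohort$weight_kg,
      AGE       = cohort$age,
      SEX01     = ifelse(cohort$sex == "male", 1, 0),
      R         = cohort$resistance_ohm,
      X         = cohort$reactance_ohm,
      Z         = cohort$impedance_ohm,
      BMI       = cohort$weight_kg / (cohort$height_cm / 100)^2,
      TANNER2   = ifelse(cohort$tanner >= 2, 1, 0)
    )
  })
  names(cols) <- tags
  tibble::as_tibble(cols)
}

term_required_fields <- function(tags) {
  unique(unlist(TERM_FIELDS[tags], use.names = FALSE))
}

# ---------------------------------------------------------------------------
# Equation registry
# ---------------------------------------------------------------------------

new_equation_spec <- function(eq_id, citation, population, coefsets,
                              sex_handling = "unisex", age_cut = NULL,
                              postscale = 1, form = "linear") {
  tags <- unique(unlist(lapply(coefsets, function(cs) setdiff(names(cs), "intercept"))))
  required <- term_required_fields(tags)
  if (sex_handling == "sex_specific") required <- union(required, "sex")
  if (!is.null(age_cut)) required <- union(required, "age")
  structure(
    list(eq_id = eq_id, citation = citation, population = population,
         sex_handling = sex_handling, age_cut = age_cut,
         postscale = postscale, form = form, coefsets = coefsets,
         terms = tags, required_fields = required),
    class = "ffm_equation"
  )
}

#' @export
print.ffm_equation <- function(x, ...) {
  cat("<ffm_equation> ", x$eq_id, " (", x$citation, ")\n",
      "  population: ", x$population, "\n",
      "  terms: ", paste(x$terms, collapse = ", "),
      if (x$sex_handling == "sex_specific") "  [sex-specific]" else "",
      if (!is.null(x$age_cut)) paste0("  [age branch at ", x$age_cut, " y]") else "",
      "\n", sep = "")
  invisible(x)
}

# Registry of the 13 literature equations plus the new obese-adolescent
# equation. Coefficients are verbatim from the source publications except
# that metre-based height terms are pre-converted to cm:
#   a*1e4*(H(m)^2/Z) == a*(H(cm)^2/Z)   and   b*H(m) == (b/100)*H(cm).
# SEX is coded male = 1, female = 0 throughout. The Wabitsch equation
# divides its linear combination by the 0.732 hydration factor; the Horie
# equation is a fat-mass formula, returned as weight minus fat mass.
build_registry <- function() {
  specs <- list(
    new_equation_spec("deurenberg91", "Deurenberg 1991",
      "healthy, 7-83 y (age-branched at 16 y)",
      coefsets = list(
        young = c(H2_over_Z = 0.406, W = 0.360, H = 0.0558, SEX01 = 0.56,
                  intercept = -6.48),
        old   = c(H2_over_Z = 0.340, H = 0.1534, W = 0.273, AGE = -0.127,
                  SEX01 = 4.56, intercept = -12.44)
      ),
      age_cut = 16),
    new_equation_spec("deurenberg90", "Deurenberg 1990",
      "healthy children and young adults, 10-25 y",
      coefsets = list(all = c(H2_over_R = 0.438, W = 0.308, SEX01 = 1.6,
                              H = 0.0704, intercept = -8.5))),
    new_equation_spec("houtkooper", "Houtkooper 1992",
      "healthy children, 10-14 y",
      coefsets = list(all = c(H2_over_R = 0.61, W = 0.25, intercept = 1.31))),
    new_equation_spec("kyle", "Kyle 2001",
      "healthy adults, 22-94 y",
      coefsets = list(all = c(H2_over_R = 0.518, W = 0.231, X = 0.130,
                              SEX01 = 4.229, intercept = -4.104))),
    new_equation_spec("suprasongsin", "Suprasongsin 1995",
      "healthy children and adults, 8-26 y",
      coefsets = list(all = c(H2_over_R = 0.524, W = 0.415, intercept = -0.32))),
    new_equation_spec("gray", "Gray 1989",
      "normal-weight and obese adults, 19-74 y",
      sex_handling = "sex_specific",
      coefsets = list(
        male   = c(H2 = 0.00139, R = -0.0801, W = 0.187, intercept = 39.830),
        female = c(H2 = 0.00151, R = -0.0344, W = 0.140, AGE = -0.158,
                   intercept = 20.387)
      )),
    new_equation_spec("lukaski", "Lukaski 1986",
      "healthy adults, 18-50 y",
      coefsets = list(all = c(H2_over_R = 0.756, W = 0.110, X = 0.107,
                              intercept = -5.463))),
    new_equation_spec("schaefer", "Schaefer 1994",
      "healthy children and adolescents, 4-19 y",
      coefsets = list(all = c(H2_over_Z = 0.65, AGE = 0.68, intercept = 0.15))),
    new_equation_spec("sun", "Sun 2003",
      "healthy adults, 12-94 y",
      sex_handling = "sex_specific",
      coefsets = list(
        male   = c(H2_over_R = 0.65, W = 0.26, R = 0.02, intercept = -10.68),
        female = c(H2_over_R = 0.69, W = 0.17, R = 0.02, intercept = -9.53)
      )),
    new_equation_spec("haroun", "Haroun 2009",
      "obese children and young adults, 5-22 y",
      coefsets = list(all = c(H2_over_Z = 1.115, intercept = -2.211))),
    new_equation_spec("horie", "Horie 2008",
      "severely obese adults (fat-mass formula)",
      form = "weight_minus_fm",
      coefsets = list(all = c(AGE = 0.13, W = 1, R = 0.09, H = -0.80,
                              intercept = 23.25))),
    new_equation_spec("lazzer", "Lazzer 2008",
      "severely obese adolescents, 10-17 y",
      coefsets = list(all = c(H2_over_Z = 0.87, intercept = 3.1))),
    new_equation_spec("wabitsch", "Wabitsch 1996",
      "obese children and adolescents, 5-17 y",
      postscale = 0.732,
      coefsets = list(all = c(H2_over_R = 0.35, AGE = 0.27, W = 0.14,
                              intercept = -0.12))),
    new_equation_spec("new_hofsteenge", "Hofsteenge 2015 (new equation)",
      "obese adolescents, 11-18 y",
      coefsets = list(all = c(H2_over_Z = 0.527, W = 0.306, intercept = -1.862)))
  )
  names(specs) <- vapply(specs, `[[`, "", "eq_id")
  specs
}

.registry <- new.env(parent = emptyenv())

registry <- function() {
  if (is.null(.registry$specs)) .registry$specs <- build_registry()
  .registry$specs
}

#' List all registered FFM prediction equations
#'
#' The built-in registry holds the 13 published equations retained by the
#' systematic selection (best equation per source study) plus the new
#' obese-adolescent equation, in stable registry order.
#'
#' @return list of `ffm_equation` objects
#' @export
list_equations <- function() registry()

#' Look up a registered equation by id
#'
#' @param eq_id equation slug, e.g. `"gray"`, `"deurenberg90"`,
#'   `"new_hofsteenge"`
#' @return an `ffm_equation`
#' @export
ffm_equation <- function(eq_id) {
  specs <- registry()
  if (!eq_id %in% names(specs)) {
    stop("unknown equation id: '", eq_id, "'; see list_equations()",
         call. = FALSE)
  }
  specs[[eq_id]]
}

#' Registry ids
#' @return character vector of registered equation ids
#' @export
equation_ids <- function() names(registry())

#' Export the registry as JSON
#'
#' @param path output file; if `NULL` the JSON string is returned
#' @return JSON string (invisibly when written to file)
#' @export
export_registry <- function(path = NULL) {
  specs <- lapply(registry(), function(eq) {
    list(eq_id = eq$eq_id, citation = eq$citation, population = eq$population,
         sex_handling = eq$sex_handling, age_cut = eq$age_cut,
         postscale = eq$postscale, form = eq$form,
         coefficients = lapply(eq$coefsets, as.list),
         height_unit = "cm", required_fields = eq$required_fields)
  })
  js <- jsonlite::toJSON(specs, auto_unbox = TRUE, pretty = TRUE,
                         null = "null", digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# ---------------------------------------------------------------------------
# Evaluation
# ---------------------------------------------------------------------------

select_coefsets <- function(eq, cohort) {
  n <- nrow(cohort)
  if (eq$sex_handling == "sex_specific") {
    if (anyNA(cohort$sex)) {
      stop("equation '", eq$eq_id, "' is sex-specific but sex is unknown ",
           "for subject(s) ", paste(cohort$id[is.na(cohort$sex)], collapse = ", "),
           call. = FALSE)
    }
    ifelse(cohort$sex == "male", "male", "female")
  } else if (!is.null(eq$age_cut)) {
    if (anyNA(cohort$age)) {
      stop("equation '", eq$eq_id, "' branches on age but age is missing ",
           "for subject(s) ", paste(cohort$id[is.na(cohort$age)], collapse = ", "),
           call. = FALSE)
    }
    ifelse(cohort$age < eq$age_cut, "young", "old")
  } else {
    rep("all", n)
  }
}

#' Evaluate one FFM prediction equation on subjects
#'
#' Computes fat-free mass in kg exactly from the registered coefficients.
#' Sex-specific equations use the male/female coefficient set per subject
#' (male = 1, female = 0 coding where sex enters as a term); age-branched
#' equations select the coefficient set by the registered age cut. The
#' Wabitsch-style post-scale divides the linear combination by the 0.732
#' hydration factor; the Horie-style form returns weight minus the evaluated
#' fat-mass expression.
#'
#' @param eq an `ffm_equation` or equation id
#' @param subjects cohort data frame (one or more rows)
#' @return numeric vector of predicted FFM, kg. Non-finite results are an
#'   error; negative or implausible (> 120 kg) predictions are returned
#'   unclipped with a warning so that validation sees equation failures.
#' @export
evaluate_equation <- function(eq, subjects) {
  if (is.character(eq)) eq <- ffm_equation(eq)
  stopifnot(inherits(eq, "ffm_equation"))
  subjects <- tibble::as_tibble(as.data.frame(subjects))

  for (f in eq$required_fields) {
    if (!f %in% names(subjects) || anyNA(subjects[[f]])) {
      bad <- if (!f %in% names(subjects)) subjects$id
             else subjects$id[is.na(subjects[[f]])]
      stop("equation '", eq$eq_id, "' requires predictor '", f,
           "', missing for subject(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }

  sets <- select_coefsets(eq, subjects)
  terms <- build_terms(subjects, eq$terms)
  pred <- numeric(nrow(subjects))
  for (set_name in unique(sets)) {
    idx <- sets == set_name
    cs <- eq$coefsets[[set_name]]
    tags <- setdiff(names(cs), "intercept")
    lin <- as.matrix(terms[idx, tags, drop = FALSE]) %*% cs[tags] +
      cs[["intercept"]]
    pred[idx] <- drop(lin) / eq$postscale
  }
  if (eq$form == "weight_minus_fm") pred <- subjects$weight_kg - pred
  if (any(!is.finite(pred))) {
    stop("non-finite prediction from '", eq$eq_id, "' for subject(s) ",
         paste(subjects$id[!is.finite(pred)], collapse = ", "), call. = FALSE)
  }
  implaus <- pred < 0 | pred > 120
  if (any(implaus)) {
    warning("equation '", eq$eq_id, "' produced ", sum(implaus),
            " implausible FFM prediction(s) (< 0 or > 120 kg); returned unclipped",
            call. = FALSE)
  }
  pred
}

#' Predict FFM for a cohort under several equations
#'
#' One prediction per (subject, equation) pair for which every required
#' predictor is present; subjects missing a required field for a given
#' equation are skipped and reported, not errors.
#'
#' @param cohort a cohort data frame
#' @param eq_ids equation ids to apply (default: whole registry)
#' @return tibble `(subject_id, eq_id, ffm_pred_kg)` with attribute
#'   `skipped`, a tibble of `(eq_id, subject_id, missing_field)` for each
#'   skipped pair.
#' @export
predict_cohort <- function(cohort, eq_ids = equation_ids()) {
  cohort <- tibble::as_tibble(as.data.frame(cohort))
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  preds <- list()
  skipped <- list()
  for (eid in eq_ids) {
    eq <- ffm_equation(eid)
    ok <- rep(TRUE, nrow(cohort))
    for (f in eq$required_fields) {
      miss <- if (!f %in% names(cohort)) rep(TRUE, nrow(cohort))
              else is.na(cohort[[f]])
      if (any(miss & ok)) {
        skipped[[length(skipped) + 1L]] <- tibble::tibble(
          eq_id = eid, subject_id = cohort$id[miss & ok], missing_field = f)
      }
      ok <- ok & !miss
    }
    if (any(ok)) {
      sub <- cohort[ok, , drop = FALSE]
      preds[[length(preds) + 1L]] <- tibble::tibble(
        subject_id = sub$id, eq_id = eid,
        ffm_pred_kg = suppressWarnings(evaluate_equation(eq, sub)))
    }
  }
  out <- dplyr::bind_rows(preds)
  skipped <- if (length(skipped)) dplyr::bind_rows(skipped)
             else tibble::tibble(eq_id = character(), subject_id = character(),
                                 missing_field = character())
  structure(out, skipped = skipped)
}
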