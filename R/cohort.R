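#' @importFrom stats lm coef pt qt rnorm runif rbinom sd var cor complete.cases t.test setNames
#' @importFrom utils read.csv write.csv write.table
NULL

# Canonical cohort column set. One row per subject; heights in cm, masses in
# kg, electrical quantities in ohm at 50 kHz.
COHORT_COLUMNS <- c(
  "id", "sex", "age", "height_cm", "weight_kg",
  "resistance_ohm", "reactance_ohm", "impedance_ohm",
  "tanner", "ffm_dxa_kg", "bmi_sds"
)

#' Assemble and validate a cohort table
#'
#' Coerces a data frame of subject records into the canonical cohort layout
#' used throughout the package and applies the physical-plausibility checks:
#' positive height, weight and resistance, non-negative reactance, impedance
#' at least as large as resistance. Impedance is back-filled as
#' \eqn{Z = \sqrt{R^2 + X_c^2}} where absent; a supplied impedance that
#' disagrees with the derived value by more than 1\% triggers a warning but
#' the supplied (measured) value wins. Rows failing a check are dropped and
#' reported in the `issues` attribute with row-numbered, machine-readable
#' reason codes.
#'
#' @param data data frame with (at least) columns `id`, `sex` (`"F"`/`"M"`),
#'   `age` (years), `height_cm`, `weight_kg`, `resistance_ohm`,
#'   `reactance_ohm`; optionally `impedance_ohm`, `tanner` (1-5),
#'   `ffm_dxa_kg`, `bmi_sds`. Missing optional columns are created as `NA`.
#' @param study_population if `TRUE` the study age window 11-18 y is
#'   enforced (violations rejected); otherwise out-of-window ages only warn.
#' @return a tibble of class `bia_cohort` with attribute `issues`, a tibble
#'   of `(row, id, code, detail)` for every rejected row.
#' @export
as_bia_cohort <- function(data, study_population = FALSE) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  mandatory <- c("id", "sex", "age", "height_cm", "weight_kg",
                 "resistance_ohm", "reactance_ohm")
  missing_cols <- setdiff(mandatory, names(data))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0L) stop("cohort is empty", call. = FALSE)
  for (col in setdiff(COHORT_COLUMNS, names(data))) data[[col]] <- NA
  data <- data[COHORT_COLUMNS]

  data$id <- as.character(data$id)
  data$sex <- normalize_sex(data$sex)
  num_cols <- setdiff(COHORT_COLUMNS, c("id", "sex"))
  for (col in num_cols) data[[col]] <- as.numeric(data[[col]])

  issues <- list()
  flag <- function(rows, code, detail) {
    if (!any(rows)) return(NULL)
    tibble::tibble(row = which(rows), id = data$id[rows], code = code,
                   detail = detail)
  }
  bad <- function(x) !is.na(x)  # helper: only flag observed violations

  rej <- rep(FALSE, nrow(data))
  checks <- list(
    list(is.na(data$sex), "bad_sex", "sex must be F or M"),
    list(bad(data$height_cm) & data$height_cm <= 0, "nonpositive_height",
         "height_cm must be > 0"),
    list(is.na(data$height_cm), "missing_height", "height_cm is required"),
    list(bad(data$weight_kg) & data$weight_kg <= 0, "nonpositive_weight",
         "weight_kg must be > 0"),
    list(is.na(data$weight_kg), "missing_weight", "weight_kg is required"),
    list(bad(data$resistance_ohm) & data$resistance_ohm <= 0,
         "nonpositive_resistance", "resistance_ohm must be > 0"),
    list(bad(data$reactance_ohm) & data$reactance_ohm < 0,
         "negative_reactance", "reactance_ohm must be >= 0")
  )
  for (ch in checks) {
    new_rows <- ch[[1]] & !rej
    issues[[length(issues) + 1L]] <- flag(new_rows, ch[[2]], ch[[3]])
    rej <- rej | ch[[1]]
  }

  # impedance: back-fill from R, X; supplied value wins but is cross-checked
  derived_z <- sqrt(data$resistance_ohm^2 + data$reactance_ohm^2)
  fill <- is.na(data$impedance_ohm) & !is.na(derived_z)
  data$impedance_ohm[fill] <- derived_z[fill]
  disagree <- !is.na(data$impedance_ohm) & !is.na(derived_z) & !fill &
    abs(data$impedance_ohm - derived_z) / derived_z > 0.01
  if (any(disagree & !rej)) {
    warning(sum(disagree & !rej), " subject(s) have supplied impedance ",
            "disagreeing with sqrt(R^2 + Xc^2) by > 1%; supplied value kept",
            call. = FALSE)
  }
  imp_low <- !is.na(data$impedance_ohm) & !is.na(data$resistance_ohm) &
    data$impedance_ohm < data$resistance_ohm * (1 - 1e-9)
  issues[[length(issues) + 1L]] <- flag(imp_low & !rej, "impedance_lt_resistance",
                                        "impedance_ohm must be >= resistance_ohm")
  rej <- rej | imp_low

  age_out <- !is.na(data$age) & (data$age < 11 | data$age > 18)
  if (study_population) {
    issues[[length(issues) + 1L]] <- flag(age_out & !rej, "age_out_of_window",
                                          "age outside 11-18 y study window")
    rej <- rej | age_out
  } else if (any(age_out & !rej)) {
    warning(sum(age_out & !rej), " subject(s) outside the 11-18 y age window",
            call. = FALSE)
  }

  tan_bad <- !is.na(data$tanner) & !(data$tanner %in% 1:5)
  issues[[length(issues) + 1L]] <- flag(tan_bad & !rej, "bad_tanner",
                                        "tanner must be an integer 1-5")
  rej <- rej | tan_bad

  issues <- dplyr::bind_rows(issues)
  if (is.null(issues) || nrow(issues) == 0L) {
    issues <- tibble::tibble(row = integer(), id = character(),
                             code = character(), detail = character())
  }
  out <- tibble::as_tibble(data[!rej, , drop = FALSE])
  if (nrow(out) == 0L) stop("all rows rejected; see issues", call. = FALSE)
  structure(out, issues = issues, class = c("bia_cohort", class(out)))
}

normalize_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("F", "FEMALE")] <- "female"
  out[x %in% c("M", "MALE")] <- "male"
  out
}

#' Issues recorded while assembling a cohort
#'
#' @param cohort a `bia_cohort`
#' @return tibble of row-numbered rejection diagnostics
#' @export
cohort_issues <- function(cohort) {
  iss <- attr(cohort, "issues")
  if (is.null(iss)) tibble::tibble(row = integer(), id = character(),
                                   code = character(), detail = character())
  else iss
}

#' Read a cohort from CSV
#'
#' Expects the canonical header (order-insensitive):
#' `id,sex,age,height_cm,weight_kg,resistance_ohm,reactance_ohm,impedance_ohm,tanner,ffm_dxa_kg,bmi_sds`
#' with sex coded `F`/`M` and missing values empty. Validation and impedance
#' back-filling are as in [as_bia_cohort()].
#'
#' @param path CSV file path
#' @param study_population enforce the 11-18 y age window
#' @return a `bia_cohort` with an `issues` attribute
#' @export
read_cohort <- function(path, study_population = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(id = "character"), na.strings = c("", "NA"))
  if (nrow(raw) == 0L) stop("empty cohort file: ", path, call. = FALSE)
  as_bia_cohort(raw, study_population = study_population)
}

#' Write a cohort to CSV
#'
#' Writes the canonical column set (UTF-8, comma separator, dot decimal);
#' the output round-trips through [read_cohort()].
#'
#' @param cohort a `bia_cohort` (or compatible data frame)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)[COHORT_COLUMNS]
  out$sex <- ifelse(out$sex == "female", "F", "M")
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.bia_cohort <- function(x, ...) {
  cat("<bia_cohort> ", nrow(x), " subjects (",
      sum(x$sex == "female"), " girls / ", sum(x$sex == "male"), " boys), ",
      sum(!is.na(x$ffm_dxa_kg)), " with DXA FFM\n", sep = "")
  NextMethod()
}
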