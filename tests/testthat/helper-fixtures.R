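# A subject at the published cohort means: H 166 cm, W 94.3 kg, age 14.4 y,
# R 505.2, Xc 62.6, Z 509.1 ohm, DXA FFM 56.1 kg.
mean_subject <- function(sex = "M", id = "mean", age = 14.4, tanner = 3,
                         impedance = 509.1) {
  tibble::tibble(
    id = id, sex = sex, age = age, height_cm = 166, weight_kg = 94.3,
    resistance_ohm = 505.2, reactance_ohm = 62.6, impedance_ohm = impedance,
    tanner = tanner, ffm_dxa_kg = 56.1, bmi_sds = NA_real_)
}

mean_cohort <- function(...) as_bia_cohort(mean_subject(...))

# Small random but physically valid cohort for property tests
random_cohort <- function(n, seed) {
  set.seed(seed)
  h <- runif(n, 150, 185)
  r <- runif(n, 400, 620)
  x <- runif(n, 45, 80)
  tibble::tibble(
    id = sprintf("r%03d", seq_len(n)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = runif(n, 11, 18), height_cm = h,
    weight_kg = runif(n, 60, 130),
    resistance_ohm = r, reactance_ohm = x,
    impedance_ohm = sqrt(r^2 + x^2),
    tanner = sample(1:5, n, replace = TRUE),
    ffm_dxa_kg = runif(n, 40, 80), bmi_sds = NA_real_) |>
    as_bia_cohort()
}
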