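---
title: "Validating BIA fat-free-mass equations against DXA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating BIA fat-free-mass equations against DXA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffmbia)
```

## The problem

Dual-energy X-ray absorptiometry (DXA) is the reference method for
partitioning body mass into fat mass and fat-free mass (FFM), but it is
expensive and confined to specialist settings. Bioelectrical impedance
analysis (BIA) is cheap, portable and safe: a 50 kHz current is passed
hand-to-foot and the tissue's resistance (R), reactance (Xc) and impedance
(Z = sqrt(R² + Xc²)) are recorded. FFM is then *predicted* from a published
regression equation on height, weight, age, sex and the electrical
quantities — and the result depends heavily on which equation is used,
because each was developed in a particular population. In obese
adolescents, whose FFM hydration and body geometry differ from the healthy
adults most equations were built on, that choice matters clinically:
weight-loss treatment aims to lose fat while preserving FFM, so FFM must be
tracked accurately.

`ffmbia` implements the standard validation workflow for this setting:

1. a registry of published FFM-BIA prediction equations (`list_equations()`),
2. accuracy/bias/RMSE evaluation of each equation against DXA
   (`validate_equations()`),
3. a lexicographic rule for naming the best equation (`rank_equations()`),
4. agreement of predicted vs DXA *change* over follow-up (`evaluate_change()`),
5. development of a new population-specific equation by forward selection
   (`forward_select()`), and
6. a moment-calibrated synthetic cohort generator (`generate_cohort()`) so
   the whole pipeline is testable and demonstrable without patient data.

## The equation registry

The registry holds 13 published equations — spanning healthy children,
healthy adults, and obese populations — plus the new obese-adolescent
equation, each as an immutable coefficient set over a fixed vocabulary of
predictor terms: the resistance index H²/R and impedance index H²/Z
(cm²/Ω, the principal BIA predictors of FFM, since conductor volume scales
with length²/impedance), H, H², W, AGE, R, Xc, Z, and SEX coded male = 1 /
female = 0.

Unit conventions are normalised once, at registration: equations published
with height in metres (both Deurenberg equations) are stored pre-converted
to cm (`a·10⁴·(H(m)²/Z) = a·(H(cm)²/Z)`; `b·H(m) = (b/100)·H(cm)`), so
evaluation has a single height unit and one fewer place for unit bugs.
Three structural variants are supported:

* **sex-specific** coefficient sets (Gray, Sun), selected per subject;
* **age-branched** sets (Deurenberg '91), switching at the registered age
  cut. The source defines branches for "≤ 15 y" and "≥ 16 y" without
  stating where 15.x-year-olds fall; we evaluate the branch on age as a
  real number with the boundary at 16.0, so 15.9 y uses the younger set;
* **post-scaled** combinations (Wabitsch), divided by the 0.732 hydration
  factor (the assumed water fraction of lean mass); and the **fat-mass
  form** (Horie), where the registered expression predicts fat mass and
  FFM is returned as weight minus it. The Horie fat-mass expression
  contains a +1·W term, so its FFM prediction is weight-independent — a
  property the tests pin down. Its coefficients are implemented verbatim;
  no published worked value exists to cross-check the resistance term, but
  evaluation at a typical obese-adolescent subject reproduces the
  validation-table mean for that equation to within a few hundred grams.

Height units for the H²/R equations published without an explicit unit
statement are taken as cm, consistent with the magnitude of the printed
coefficients (a metre-based coefficient would be ~10⁴ larger).

Predictions are deterministic, and deliberately **unclipped**: a negative
or implausible (> 120 kg) FFM is returned with a warning rather than
truncated, because a validation exercise must see equation failures as
they are.

## Accuracy metrics

For subject *i* with predicted FFM *p*ᵢ and DXA FFM *d*ᵢ the relative
error is eᵢ = 100·(pᵢ − dᵢ)/dᵢ (%). With cutoff *c* (default 5%, the
conventional bound on technical measurement error; 2.5% is the stricter
clinically motivated alternative and is configurable):

* **accurate**: |eᵢ| ≤ c — the boundary counts as accurate (the verbal
  definition "within c%" leaves the boundary open; inclusive is the
  natural closed reading and is applied consistently);
* **under/over**: eᵢ < −c / eᵢ > +c — the three classes partition the
  cohort for any cutoff;
* **bias** = mean(eᵢ), the mean of per-subject percentage errors (not the
  percentage difference of the means — the two differ under heterogeneous
  denominators);
* **extreme errors** = min(eᵢ) and max(eᵢ), reported regardless of sign;
* **RMSE** = sqrt(mean((pᵢ − dᵢ)²)) in kg, with population denominator
  *n*, following the verbal recipe "mean of the squared differences, then
  the root".

Full precision is kept internally; rendered tables round percentages and
kg to one decimal.

## The best-equation rule

An equation that is accurate overall but only for one sex is not clinically
useful, so ranking is lexicographic: (1) highest percentage accurate,
(2) smallest girl–boy gap in accuracy, (3) smallest |bias|, (4) smallest
RMSE. The source criteria give the order but no tie tolerances; we treat
accuracies within 2 percentage points as tied at criteria 1–2 and biases
within 0.5 points at criterion 3 (both configurable), so that later
criteria can actually decide — with exact comparisons, criterion 1 would
almost always be decisive on its own. `rank_equations()` returns the full
decision trace; surviving ties resolve to the first candidate in the
stable accuracy-sorted order.

## Change agreement

For matched baseline/follow-up measurements, `evaluate_change()` computes
each subject's DXA FFM change and predicted FFM change, and tests the
paired differences with a two-sided paired t-test. When every difference
is identical the t statistic is undefined (zero variance); the result is
flagged `degenerate` with `p = NA` rather than inventing a p-value.

## Developing a new equation

`forward_select()` implements greedy forward selection over the candidate
set {W, AGE, H, BMI, H²/R, H²/Z, R, Z, Xc, SEX, Tanner dummy}: at each
step the candidate with the largest R² gain is adopted; selection stops
when the gain falls below 0.01 (configurable) — i.e. when further
variables "do not further improve explained variance" in any practically
relevant amount. Selection is on explained variance only; coefficient
p-values are reported for inspection but never drive selection. Candidate
comparisons are made on the complete-case subject set over all usable
candidates, so every step compares models on identical data. The
resistance and impedance indices are near-collinear by construction;
a candidate whose addition makes the design rank-deficient yields no
usable gain and is never adopted, while an explicit rank-deficient request
to `fit_ols()` errors naming the collinear terms.

Reported fit quantities: R² = 1 − SSE/SST; SEE = sqrt(SSE/(n − p − 1))
with p slope terms (the residual standard deviation on the fitted scale,
kg); and internal accuracy, the percentage of subjects whose *fitted* FFM
falls within the cutoff of their DXA FFM. Internal accuracy is optimistic
by construction (same data fit and evaluated) — a developed equation still
awaits external validation. `subgroup_stability()` refits the chosen term
set within sex or pubertal subgroups (Tanner 1–2 vs 3–5 for "early/late";
the pre-/pubertal dummy uses stage 1 vs ≥ 2) and reports per-group R²,
skipping groups with n ≤ p + 2.

## The synthetic cohort generator

`generate_cohort()` draws obese-adolescent cohorts with the documented
second-moment structure: sex Bernoulli(61/103); age normal 14.4 (1.7) y
truncated to 11–18; height normal within sex (girls 164.0 (6.0), boys
169.0 (12.0) cm); weight normal 94.3 (15.7) kg, correlated 0.5 with height
within sex and truncated above 40 kg; reactance normal 62.6 (7.7) Ω. The
generative truth for body composition is the linear model

FFM = 0.527·(H²/Z) + 0.306·W − 1.862 + ε,  ε ~ N(0, 2.85 kg),

with the impedance index ZI = H²/Z conditionally normal given weight.
Impedance is derived physically (Z = H²/ZI), reactance is drawn, and
resistance follows as R = sqrt(Z² − Xc²); draws violating Z > Xc or a
truncation bound are rejection-resampled with a 1000-round cap, keeping
the distributions near-normal. Tanner stage is assigned by an age
threshold (12.5 y) with a 15% flip probability, purely to exercise the
subgroup machinery.

**Calibration.** The marginal moments of ZI and its correlation with
weight are not published anywhere; they are *derived* constants, chosen
once by moment matching so that the generative model reproduces the
published summary statistics. With sd(W) = 15.7, sd(ZI) = 9.74 and
corr(ZI, W) = 0.78:

* Var(FFM) = 0.527²·9.74² + 0.306²·15.7² + 2·0.527·0.306·0.78·9.74·15.7
  + 2.85² = 96.02, i.e. sd 9.80 kg (target 9.8);
* mean FFM = 0.527·55.2 + 0.306·94.3 − 1.862 = 56.08 kg (target 56.1);
* single-predictor R² of FFM on ZI = 0.821 (target 0.82) and two-predictor
  R² = 1 − 2.85²/96.02 = 0.915 (target 0.92).

`cohort_calibration()` exposes this variance decomposition in closed form
and the tests verify it both analytically and by simulation. Mean
impedance is *not* forced: it emerges from Z = H²/ZI at roughly 500–520 Ω,
near but not exactly at the published 509 Ω — a documented approximation,
accepted because the regression structure, not the raw impedance scale, is
what the downstream analyses consume.

`generate_followup()` adds a six-month DXA FFM change ~ N(1.49, 2.72) kg
per subject, updates weight by the FFM change plus an independent
fat-mass change ~ N(0, 2) kg (an artifact assumption — fat change is not
modelled mechanistically), re-derives ZI by inverting the generative
equation at the new FFM with a fresh residual, and recomputes the BIA
fields.

**What passing tests do and do not show.** The generator reproduces second
moments and the linear FFM structure; it does not emulate growth curves,
maturation dynamics, non-Gaussian residuals, device-specific error, or
non-Caucasian population differences. In particular, under Gaussian
residuals of sd 2.85 kg at FFM ≈ 56 kg, about 68% of subjects fall within
±5% — so the generator cannot (and is not asked to) reproduce the higher
internal accuracy a real development cohort showed; the true residual
distribution there is unknown. Equation rankings computed on synthetic
cohorts favour the equation sharing the generator's structure by
construction and say nothing about relative merit on real patients.

## Numerical choices and problem sizes

* Impedance supplied in the data always wins over the value derived from
  R and Xc; a > 1% disagreement warns, respecting measured data while
  surfacing inconsistency.
* Metrics use exact floating-point comparisons at the cutoff boundary
  (inclusive); no rounding happens before classification or averaging.
* Parameter-recovery demonstrations use n = 10 000 (coefficient Monte
  Carlo error ≈ 0.005, comfortably inside the ±0.02 bands we check) with
  a fixed seed; unbiasedness at the study size uses 200 replicates of
  n = 103, whose Monte Carlo standard errors (~0.003 for the index
  coefficient) make a 2-SE check meaningful. Module-level tests use
  smaller cohorts (n = 150–3000) with proportionally wider bands.
* CSV is UTF-8, comma-separated, dot decimal, missing values empty; JSON
  reports keep full precision and rerun byte-identically for identical
  inputs.

## Limitations

The registry covers equations selected for 50 kHz hand-to-foot BIA in
healthy or obese populations including both sexes; device-internal FFM
algorithms and bioimpedance spectroscopy are out of scope. Published
validation tables for real cohorts depend on the individual patient
records, which are not public, so they cannot be reproduced here — the
package instead validates against analytic identities and its own
calibrated generator. Any newly developed equation should be externally
validated before clinical use.
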