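---
title: "Cutpoint scans for nonlinear mortality risk: models, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cutpoint scans for nonlinear mortality risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hrscan)
```

## The scientific problem

In critically ill patients, admission risk factors such as glycated
hemoglobin (HbA1c, a 2-3 month proxy of average glycemia) and body mass
index (BMI) need not act linearly on in-hospital mortality. HbA1c may be
harmless over most of its range and become dangerous only beyond a
threshold; BMI famously shows an "obesity paradox" in the ICU — elevated
mortality at low BMI, no excess in the overweight range, and apparent
protection at high BMI. `hrscan` implements a procedure for mapping such
relationships with standard proportional-hazards machinery:

1. **Cutpoint scan.** For each cutoff `c` on a grid (BMI 20 to 35 by 0.5 —
   31 tested cutpoints; HbA1c 4.5 to 12 by 0.25 by default), the cohort is
   dichotomized at `c` and a Cox model is fit to the group indicator plus
   adjustment covariates (APACHE II by default). Each fit contributes one
   adjusted log hazard ratio with its standard error.
2. **Spline smoothing.** The log-HR-versus-cutoff points are smoothed by
   weighted least squares on a restricted (natural) cubic spline with four
   knots; weights are the inverse variances.
3. **Simultaneous band.** A confidence band
   `exp(fitted ± z[1 - α/(2m)] · SE_fit)` is drawn, with the Bonferroni
   multiplicity `m` equal to the number of usable tested cutoffs.
4. **Threshold call.** Maximal grid intervals where the band excludes
   HR = 1 are reported as risk (lower bound above 1) or protection (upper
   bound below 1); the headline threshold is the first boundary of the
   first risk interval.

The scan estimand deserves emphasis: the value at cutoff `c` compares
*everyone below `c` with everyone above `c`*. It is a global contrast, not
the local hazard ratio at `c`. Consequences of this are discussed under
*Known limitations*.

## The Cox engine

All hazard ratios come from the package's own maximum partial-likelihood
fitter (`fit_cox()`): Newton-Raphson from `beta = 0` with step-halving (up
to 10 halvings), convergence when the score sup-norm drops below `tol`
(default 1e-8) or the relative log-likelihood change vanishes, a maximum of
50 iterations, and a monotone-likelihood (separation) diagnostic that flags
any coefficient drifting beyond |beta| > 15 as non-convergence instead of
returning a spurious estimate. Scan points whose fit fails this way are
dropped from smoothing and flagged in the output.

Ties are handled by the Efron correction by default — ICU follow-up is
recorded at day resolution and tied deaths are common in real data, where
Efron is less biased. Breslow is retained both for speed and because two
classical identities hold only in Breslow form: the score test of a binary
group indicator equals the log-rank chi-square (exactly so in the absence
of tied event times), and duplicating every record leaves the estimate
exactly unchanged. The test-suite pins the fitter to a brute-force grid
search of the partial likelihood on small datasets and to an independent
reference implementation on cohort-sized ones, and verifies the score/
log-rank identity to 1e-8.

No penalization or Firth correction is applied; extreme cutoffs that
separate the data are excluded (with the `min_events_per_group = 5` rule
below) rather than shrunk.

## The simultaneous band: why not naive weighted least squares

Scan points at neighbouring cutoffs are computed on almost the same data —
moving the cutoff by one grid step reclassifies only a handful of patients
— so their sampling errors are strongly positively correlated. Treating
the `m` points as independent observations in the weighted least-squares
covariance `(B'WB)^-1` understates the variance of the fitted curve by
roughly the ratio of `m` to the spline's degrees of freedom. Measured under
a null cohort (no covariate effects), a band built that way excludes HR = 1
somewhere on the grid in about a third of replications — at a nominal
simultaneous 5% — which defeats the purpose of the Bonferroni correction.

`smooth_scan()` therefore estimates the full `m × m` covariance of the scan
points with an influence-function (infinitesimal-jackknife) argument: the
per-subject dfbeta values of each cutoff's Cox fit (`cox_dfbeta()`, exact
against the reference implementation) are cross-multiplied,
`Cov(b_c, b_c') = Σ_i dfbeta_c(i) · dfbeta_c'(i)`, and this covariance is
propagated through the spline's linear smoother. Everything else — the
inverse-variance weights, the four-knot basis, the Bonferroni multiplier
over the `m` tested cutoffs — is unchanged. Under the same null
simulation the robust band excludes HR = 1 in about 1-2% of replications,
i.e. it is conservative, as a Bonferroni band should be. The naive
covariance remains available as `se_method = "independence"`.

Numerical details: knots sit at the 5th/35th/65th/95th percentiles of the
usable cutoffs (Harrell's default placement, keeping the linear tails
stable); the spline is evaluated on 201 points spanning the scan range;
coincident knots or a singular design raise errors rather than warnings.
Weighting by `1/se^2` keeps near-tail cutoffs, whose dichotomizations are
extremely noisy, from dominating the fit.

## The synthetic cohort generator

No patient-level data accompany the study this package replicates, so
validation rests on a generator (`generate_cohort()`) that reproduces the
statistical structure the analysis assumes:

* **Covariates.** BMI is truncated normal (mean 26.1, SD 6.6 kg/m², bounds
  13-60); HbA1c is truncated log-normal (median 5.75%, log-SD 0.15, bounds
  3.5-18) — the positive skew matches the reported median/IQR summaries;
  hemoglobin is truncated normal. The three are coupled by a Gaussian
  copula whose pairwise correlations are the square roots of the target
  squared correlations (defaults r² = 0.05 for BMI-HbA1c and 0.026 for
  HbA1c-hemoglobin, the weak dependencies reported for the cohort).
  APACHE II is truncated normal (mean 20.7, SD 8.6, bounds 0-71). Age,
  sex, SOFA, lactate, C-reactive protein, glucose and treatment flags are
  filled with clinically plausible marginals (flags through logistic models
  on the APACHE z-score) — they exist for the table builder, not for the
  hazard model.
* **Survival.** The death time is exponential with log-hazard
  `log(baseline) + f_hba1c(HbA1c) + f_bmi(BMI) + 0.10 · APACHE II`; an
  independent exponential discharge time censors it, and follow-up is
  capped at 365 days. Exponential (piecewise-constant) truth is sufficient
  because Cox estimation is baseline-free, and it admits closed-form
  inverse-transform sampling. Censoring independent of covariates is the
  weakest assumption testable here; the study reports no discharge model.
* **Effects.** `threshold_effect(9.3, log(1.74))` — a step of hazard ratio
  1.74 at and above an HbA1c of 9.3% — and a shallow U-shaped
  `piecewise_effect(c(24, 30), c(-0.075, 0, -0.075))` for BMI are the
  default truths, mirroring the relationships the scan is meant to
  recover. Effects are continuous piecewise-linear (anchored at zero at the
  first breakpoint) or step functions; evaluation extrapolates with the
  nearest segment and never fails.
* **Calibration.** With those defaults, `baseline_hazard_per_day = 0.00196`
  and `discharge_rate_per_day = 0.0220` were solved once by large-n
  simulation so that the default 199-patient cohort reproduces the study's
  43.2% in-hospital mortality and ~16-day median follow-up. The calibration
  is part of the frozen defaults, not a tuning knob.
* **Reproducibility.** One seed drives four derived substreams
  (covariates, death times, discharge times, treatment flags), so
  regenerating any stage leaves the others untouched; identical
  configuration and seed give a bit-identical cohort.

What the generator does **not** emulate: length-of-stay dynamics, organ
failure trajectories, time-varying covariates, informative discharge, or
the day-resolution rounding of real follow-up (simulated times are
continuous, so ties are rare). Passing simulation tests therefore
demonstrates correctness of the estimation machinery under the stated
model, not robustness to violations real ICU data may exhibit.

## Validation experiments

Three simulation experiments, with configurations frozen alongside the
generator defaults, probe the full scan procedure. Problem sizes were
chosen so each experiment completes in minutes on one CPU.

* **Threshold localization** — 200 cohorts of n = 2000 with the step truth
  (9.3%, HR 1.74), BMI effect disabled (the default BMI effect is
  copula-correlated with HbA1c and would confound the configured truth),
  and an HbA1c marginal of log-median 6.0, log-SD 0.28, so about 6% of
  patients exceed the true threshold — a diabetes-enriched tail giving the
  dichotomized comparison at 9.3 high power. Reported: the median headline
  threshold and the median adjusted HR of the dichotomy at 9.3.
* **Null coverage** — 500 default-size cohorts with all covariate effects
  removed and the baseline hazard raised to 0.0167/day so the null cohorts
  keep the study's ~43% mortality. Reported: the share of cohorts in which
  the band excludes HR = 1 anywhere.
* **U-shape pattern** — 200 cohorts of n = 2000 with the piecewise BMI
  truth only. Reported: how often the band shows risk at BMI 21, covers 1
  at 27, and shows protection at 34.

## Known limitations

Two limitations are structural, and worth stating bluntly because the
validation suite measures them honestly rather than hiding them.

* **The headline threshold is biased toward the covariate's center.** For
  a true step at 9.3, the dichotomized contrast at any cutoff *below* 9.3
  is still positive — the high group contains every affected patient,
  diluted — with magnitude `log(1 + q_c (HR-1))`, where `q_c` is the
  affected fraction of the high group. As power grows, the band clears
  HR = 1 at cutoffs progressively further left of the true step, and the
  first-exclusion boundary drifts with it: at n = 2000 the median headline
  sits near 7.9, about 1.4 units left of the configured 9.3. The interval
  reported by `detect_threshold()` reliably *contains* the step; its left
  boundary is not a consistent estimator of the step's location. Users
  wanting a change-point estimate should read the fitted curve, not the
  first band crossing.
* **The scan cannot show a U-shape as risk/null/protection.** The scan
  value at cutoff `c` compares means below versus above `c`. Under any
  U-shaped truth (hazard elevated in the low tail, reduced in the high
  tail) that contrast is strictly positive across the entire grid: at a
  middle cutoff the low side contains the risk tail and the high side the
  protective tail, so the two tails reinforce rather than cancel. With
  n = 2000 the band accordingly shows "risk" at BMI 21, 27 *and* 34 — the
  value at 34 being, equivalently, the protection of the heaviest group,
  which is how such output is conventionally narrated. A sign pattern of
  risk/null/protection at 21/27/34 is an attribute of the *local* hazard
  ratio function (a spline of the covariate inside the Cox model), not of
  the dichotomization scan, and no choice of slopes, marginals or band
  construction makes the scan produce it. The stratified group model
  (`group_cox()`, bounds 20/24/35) is the package's instrument for the
  paradox-style contrast, and recovers it cleanly.

Further non-goals: no maximally-selected-rank-statistic cutpoint
selection, no Šidák or permutation multiplicity corrections, no
time-varying covariates, stratified baselines, frailty terms or
proportionality diagnostics, no competing-risks treatment of discharge
(discharge is censoring throughout), and no confidence bands for the
adjusted survival curves.

## Other design decisions

* **Adjusted survival curves** use corrected group prognosis: for each BMI
  stratum, the Cox-predicted individual curves of *all* cohort members
  (group indicators forced to the stratum, personal adjustment covariates
  kept) are averaged. With vanishing coefficients every stratum collapses
  to the Breslow baseline survival, and the curves are invariant to affine
  rescaling of the adjustment covariates.
* **Classification boundaries.** ADA glucose tolerance: normal < 5.7%,
  prediabetes [5.7, 6.5), diabetes ≥ 6.5%, with a known diabetes history
  overriding the measurement. WHO BMI bins are half-open and
  lower-inclusive ([18.5, 25), [25, 30), [30, 40), [40, ∞)), so a BMI of
  exactly 40 is extreme obesity and 24.95 is normal weight. BMI strata for
  the group model are likewise lower-inclusive (23.95 falls in 20-23.9,
  24.0 in 24-34.9).
* **Descriptive tests.** Student t with pooled variance for
  normal-summarized variables, Mann-Whitney U for skewed ones, Pearson
  chi-square without continuity correction for categoricals; percentages
  are computed within survival group and rounded to one decimal. A flag
  that never occurs is summarized as 0 (0.0) with the test skipped and
  noted.
* **Scan bookkeeping.** The grid includes both endpoints; cutoffs leaving
  fewer than five events on either side, degenerate cuts, and
  non-converged fits are flagged unusable and excluded from smoothing (at
  least four usable points are required); identical cohort and
  specification give bit-identical scan output.
* **Pipeline.** `run_study()` writes every artifact (cohort, table, scan
  points, bands, threshold calls, group model, adjusted curves) as plain
  UTF-8 CSV/JSON with a manifest carrying the configuration echo, seed,
  per-stage timings and an MD5 checksum per file; re-running a
  configuration reproduces the numeric outputs byte for byte, and a stage
  failure removes partial outputs.
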