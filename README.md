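# hrscan

Cutpoint scans and spline-smoothed hazard ratios for ICU survival cohorts.

## What it is for

Continuous admission risk factors in critical care often act nonlinearly on
in-hospital mortality: glycated hemoglobin (HbA1c) may matter only beyond a
threshold, while BMI shows the "obesity paradox" — excess mortality at low
BMI, none in the overweight range, apparent protection at high BMI. `hrscan`
is for biostatisticians and intensivists who want to map such relationships
with proportional-hazards machinery rather than assume linearity:

* **Cutpoint scan**: dichotomize the risk factor at every cutoff on a grid
  (BMI 20–35 by 0.5 → 31 tested cutpoints; HbA1c 4.5–12 by 0.25), fit an
  adjusted Cox model at each cut, and trace the adjusted hazard ratio
  `HR(c)` across cutoffs.
* **Spline smoothing with simultaneous bands**: smooth `log HR(c)` with a
  four-knot restricted cubic spline by inverse-variance weighted least
  squares, and draw a Bonferroni-corrected band
  `exp(fitted ± z[1−α/(2m)] · SE_fit)` over the `m` tested cutoffs.
  `SE_fit` uses an influence-function estimate of the full between-cutoff
  covariance — scan points at neighbouring cutoffs share almost all
  subjects, and ignoring that correlation destroys the band's coverage.
* **Threshold calls**: report the covariate ranges where the band excludes
  HR = 1 (risk or protection) and a headline boundary.
* Supporting machinery: a from-scratch Cox partial-likelihood engine
  (Breslow/Efron ties, Newton–Raphson with step-halving, separation
  diagnostics, Breslow baseline, dfbeta influence values), Kaplan–Meier and
  log-rank estimation, covariate-adjusted survival curves by BMI strata
  (corrected group prognosis), a survivors-vs-nonsurvivors descriptive
  table with ADA glucose-tolerance and WHO BMI categories, and a calibrated
  synthetic ICU-cohort generator (~200 patients, ~43% mortality, weakly
  correlated BMI and HbA1c, configurable threshold and U-shaped effects)
  for validation by simulation.

## Worked example

Simulate a default 199-patient cohort and inspect it:

```r
library(hrscan)
cohort <- generate_cohort(cohort_config(), seed = 42)
build_table1(cohort)
#> Cohort characteristics by survival: 111 survivors, 88 nonsurvivors
#> Overall in-hospital mortality: 88/199 (44.2%)
#> No known DM history: 159 (79.9%); among them prediabetes 53 (33.3%), unrecognized DM 28 (17.6%)
#>  variable   survivors      nonsurvivors   p
#>  age        57.4 ± 17.1    58.3 ± 14.6    0.710
#>  apache2    18.9 ± 7.3     23.2 ± 8.0     <0.001
#>  bmi        26.8 ± 5.9     25.7 ± 6.1     0.183
#>  ...
```

Stratify BMI as in the paradox analyses (reference BMI < 20, adjusted for
APACHE II and HbA1c) — mortality falls with increasing BMI:

```r
group_cox(cohort, bounds = c(20, 24, 35))
#> Stratified Cox model on bmi (adjusted for apache2, hba1c)
#>      group   n events    hr lower upper        p
#>     bmi<20  31     18 1.000    NA    NA       NA
#>  bmi 20-24  41     17 0.308 0.154 0.617 0.000891
#>  bmi 24-35 110     46 0.425 0.242 0.748 0.003010
#>    bmi>=35  17      7 0.442 0.182 1.075 0.071800
```

Scan HbA1c on a larger simulated cohort carrying a configured step of
HR 1.74 at HbA1c ≥ 9.3%:

```r
cfg <- cohort_config(n_patients = 2000,
                     hba1c_dist = list(meanlog = log(6.0), sdlog = 0.28,
                                       lo = 3.5, hi = 18),
                     bmi_effect = null_effect())
cohort <- generate_cohort(cfg, seed = 7)
spec <- scan_spec("hba1c", 4.5, 12, 0.25, direction = "risk-above",
                  adjust_for = "apache2")
band <- smooth_scan(run_scan(cohort, spec))
detect_threshold(band)
#> threshold call: band excludes HR = 1 on
#>   [7.42, 10.8]  (risk)
#>   headline threshold: 7.42
```

The band flags the high-HbA1c range as a mortality risk (the configured
step lies inside the flagged interval; the interval's left edge sits below
the true step — see the methods vignette on why the first band crossing is
not a change-point estimator). The dichotomized adjusted model at the true
cut, with a Bonferroni-corrected interval over the 31 tested cutoffs:

```r
d <- survival_data(cohort$time, cohort$event,
                   cbind(hi = as.integer(cohort$hba1c >= 9.3),
                         apache2 = cohort$apache2))
round(wald_interval(fit_cox(d), "hi", alpha = 0.05 / 31), 3)
#>    hr lower upper
#> 1.919 1.321 2.787
```

A full study replica (cohort → table → both scans → bands → threshold calls
→ stratified model → adjusted curves, all as CSV/JSON with a checksummed
manifest) is one call — or one shell command via
`inst/scripts/run_study.R`:

```r
run_study(run_config(mode = "simulate", seed = 1, out_dir = "run1"))
```

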