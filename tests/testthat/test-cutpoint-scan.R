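test_that("dichotomize follows the two directional conventions", {
  expect_identical(dichotomize(c(22, 25), 23, "risk-below"), c(1L, 0L))
  expect_identical(dichotomize(c(9.2, 9.4), 9.3, "risk-above"), c(0L, 1L))
  expect_error(dichotomize(c(5, 6), 4, "risk-above"), "degenerate")
  expect_error(dichotomize(c(5, 6), 10, "risk-below"), "degenerate")
})

test_that("the BMI specification tests 31 inclusive cutoffs", {
  sp <- bmi_scan_spec()
  expect_length(sp$grid, 31)
  expect_equal(range(sp$grid), c(20, 35))
  expect_error(scan_spec("bmi", 20, 21, 0.5), "4")
})

test_that("scans are deterministic and respect group-count bookkeeping", {
  ch <- generate_cohort(cohort_config(), seed = 14)
  sp <- bmi_scan_spec()
  s1 <- run_scan(ch, sp)
  s2 <- run_scan(ch, sp)
  expect_identical(s1, s2)
  expect_true(all(s1$n_low + s1$n_high == nrow(ch)))
  expect_true(all(s1$events_low + s1$events_high == sum(ch$event)))
  expect_true(all(s1$hr[s1$converged] == exp(s1$loghr[s1$converged])))
})

test_that("flipping the scan direction negates every log hazard ratio", {
  ch <- generate_cohort(cohort_config(), seed = 15)
  lo <- run_scan(ch, scan_spec("bmi", 20, 35, 0.5, direction = "risk-below",
                               adjust_for = "apache2"))
  hi <- run_scan(ch, scan_spec("bmi", 20, 35, 0.5, direction = "risk-above",
                               adjust_for = "apache2"))
  ok <- lo$usable & hi$usable
  expect_gt(sum(ok), 20)
  expect_equal(lo$loghr[ok], -hi$loghr[ok], tolerance = 1e-6)
  expect_equal(lo$se[ok], hi$se[ok], tolerance = 1e-6)
})

test_that("duplicating every record leaves the log-HRs fixed and shrinks the SEs", {
  ch <- generate_cohort(cohort_config(n_patients = 150), seed = 16)
  ch2 <- rbind(ch, ch)
  sp <- bmi_scan_spec()
  # exact duplication invariance is a property of the Breslow likelihood;
  # Efron's within-tie downweighting perturbs it slightly
  s1 <- run_scan(ch, sp, ties = "breslow")
  s2 <- run_scan(ch2, sp, ties = "breslow")
  ok <- s1$usable & s2$usable
  expect_equal(s1$loghr[ok], s2$loghr[ok], tolerance = 1e-6)
  expect_true(all(s2$se[ok] < s1$se[ok]))
})

test_that("a flat zero scan smooths to HR identically 1 with a symmetric band", {
  sp <- bmi_scan_spec()
  pts <- fake_scan_points(sp$grid, rep(0, 31), rep(0.2, 31), sp)
  bd <- smooth_scan(pts, se_method = "independence")
  expect_equal(bd$hr, rep(1, nrow(bd)), tolerance = 1e-12)
  expect_equal(log(bd$upper), -log(bd$lower), tolerance = 1e-12)
})

test_that("the natural spline reproduces an exactly linear scan", {
  sp <- bmi_scan_spec()
  pts <- fake_scan_points(sp$grid, 0.05 * (sp$grid - 27), rep(0.15, 31), sp)
  bd <- smooth_scan(pts, se_method = "independence")
  expect_equal(bd$loghr_fit, 0.05 * (bd$cutoff - 27), tolerance = 1e-8)
})

test_that("the Bonferroni multiplier uses the tested-cutoff count", {
  sp <- bmi_scan_spec()
  pts <- fake_scan_points(sp$grid, rep(0, 31), rep(0.2, 31), sp)
  bd <- smooth_scan(pts, se_method = "independence")
  expect_equal(attr(bd, "m"), 31)
  expect_equal(attr(bd, "zcrit"), qnorm(1 - 0.05 / 62))
  # wider everywhere than the pointwise 95% band on the same fit
  half_bonf <- log(bd$upper) - bd$loghr_fit
  half_plain <- qnorm(0.975) * bd$se_fit
  expect_true(all(half_bonf > half_plain))
})

test_that("threshold calls report band exclusions and the headline boundary", {
  sp <- hba1c_scan_spec()
  grid <- seq(4.5, 12, length.out = 201)
  shift <- 0.3 * (grid >= 9.3) - 0.25 * (grid <= 5.5)
  bd <- structure(data.frame(cutoff = grid, loghr_fit = shift,
                             se_fit = 0.05, hr = exp(shift),
                             lower = exp(shift - 0.2), upper = exp(shift + 0.2)),
                  class = c("spline_band", "data.frame"),
                  m = 31, alpha = 0.05, zcrit = 3, spec = sp)
  tc <- detect_threshold(bd)
  expect_equal(nrow(tc$intervals), 2)
  expect_equal(tc$headline, min(grid[grid >= 9.3]))
  risk <- tc$intervals[tc$intervals$side == "risk", ]
  expect_equal(risk$to, 12)
  prot <- tc$intervals[tc$intervals$side == "protection", ]
  expect_equal(prot$from, 4.5)
  # a null band yields an empty call
  null_bd <- bd
  null_bd$lower <- exp(-0.2)
  null_bd$upper <- exp(0.2)
  null_bd$hr <- 1
  tc0 <- detect_threshold(null_bd)
  expect_equal(nrow(tc0$intervals), 0)
  expect_true(is.na(tc0$headline))
})

test_that("BMI strata use lower-inclusive bounds with the first group as reference", {
  ch <- generate_cohort(cohort_config(n_patients = 400), seed = 18)
  ch$bmi[1:4] <- c(18, 22, 30, 40)
  gf <- group_cox(ch, bounds = c(20, 24, 35))
  expect_equal(gf$membership[1:4], c(1L, 2L, 3L, 4L))
  ch$bmi[5:6] <- c(23.95, 24.0)
  gf2 <- group_cox(ch, bounds = c(20, 24, 35))
  expect_equal(gf2$membership[5:6], c(2L, 3L))
  expect_equal(gf2$groups$hr[1], 1)
  expect_equal(nrow(gf2$groups), 4)
  expect_equal(sum(gf2$groups$n), nrow(ch))
  # empty stratum is named in the error
  ch3 <- ch
  ch3$bmi <- pmin(ch3$bmi, 34)
  expect_error(group_cox(ch3, bounds = c(20, 24, 35)), ">=35")
})

test_that("group-model Wald p-values are uniform under an identical hazard", {
  cfg <- cohort_config(hba1c_effect = null_effect(), bmi_effect = null_effect(),
                       apache_loghr_per_point = 0,
                       baseline_hazard_per_day = 0.0167)
  pvals <- vapply(1:500, function(s) {
    ch <- generate_cohort(cfg, seed = 40000 + s)
    gf <- tryCatch(group_cox(ch, bounds = c(20, 24, 35)),
                   error = function(e) NULL)
    if (is.null(gf) || !gf$fit$converged) return(NA_real_)
    gf$groups$p[2]
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  expect_gt(length(pvals), 450)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
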