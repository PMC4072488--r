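test_that("partial log-likelihood matches hand-evaluated risk-set terms", {
  d <- survival_data(c(1, 2), c(1, 1), cbind(x = c(1, 0)))
  expect_equal(partial_loglik(d, 0), log(1 / 2))
  expect_equal(partial_loglik(d, 1), 1 - log(exp(1) + 1))
  tied <- survival_data(c(1, 1), c(1, 1), cbind(x = c(1, 0)))
  expect_equal(partial_loglik(tied, 0, ties = "breslow"), 2 * log(1 / 2))
  # at beta = 0 the tie corrections need not agree, but on tie-free data
  # Breslow and Efron are one and the same likelihood
  expect_equal(partial_loglik(d, 0.7, "efron"), partial_loglik(d, 0.7, "breslow"))
  expect_error(partial_loglik(d, Inf), "finite")
})

test_that("fit_cox maximizes the partial likelihood (brute-force grid oracle)", {
  for (f in small_cox_fixtures()) {
    d <- survival_data(f$time, f$event, cbind(x = f$x))
    for (ties in c("breslow", "efron")) {
      fit <- fit_cox(d, ties = ties)
      if (!fit$converged) next  # separation handled separately
      oracle <- grid_max_loglik(f$time, f$event, f$x, ties = ties)
      expect_lt(abs(fit$beta - oracle), 1e-3)
      expect_gte(fit$loglik, fit$loglik_null - 1e-8)
    }
  }
})

test_that("a symmetric tied pair has its maximum exactly at beta = 0", {
  d <- survival_data(c(1, 1), c(1, 1), cbind(x = c(1, 0)))
  for (ties in c("breslow", "efron"))
    expect_equal(unname(fit_cox(d, ties = ties)$beta), 0)
})

test_that("the fit is invariant to the ordering of subjects", {
  f <- list(time = c(2, 4, 4, 6, 7), event = c(1, 1, 0, 1, 0),
            x = c(1, 1, 0, 0, 1))
  d1 <- survival_data(f$time, f$event, cbind(x = f$x))
  set.seed(5)
  p <- sample(5)
  d2 <- survival_data(f$time[p], f$event[p], cbind(x = f$x[p]))
  expect_equal(fit_cox(d1)$beta, fit_cox(d2)$beta)
})

test_that("Breslow and Efron agree to 1e-10 on tie-free data", {
  set.seed(77)
  n <- 60
  d <- survival_data(rexp(n) + 0.01, rbinom(n, 1, 0.6),
                     cbind(x = rnorm(n), z = rbinom(n, 1, 0.4)))
  fb <- fit_cox(d, ties = "breslow")
  fe <- fit_cox(d, ties = "efron")
  expect_equal(fb$beta, fe$beta, tolerance = 1e-10)
  expect_equal(fb$loglik, fe$loglik, tolerance = 1e-10)
})

test_that("coefficients, errors and likelihoods match an independent fitter", {
  skip_if_not_installed("survival")
  ch <- generate_cohort(cohort_config(n_patients = 400), seed = 8)
  d <- survival_data(ch$time, ch$event,
                     cbind(bmi = ch$bmi, apache2 = ch$apache2,
                           hba1c = ch$hba1c))
  for (ties in c("efron", "breslow")) {
    fit <- fit_cox(d, ties = ties)
    ref <- survival::coxph(survival::Surv(time, event) ~ bmi + apache2 + hba1c,
                           data = ch, ties = ties)
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
    expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-6)
  }
})

test_that("degenerate designs and separation are reported, not returned silently", {
  expect_error(survival_data(c(1, 2), c(1, 1), cbind(x = c(1, 1))),
               "degenerate|constant")
  # perfectly separated groups: monotone likelihood
  d <- survival_data(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 1, 1, 1),
                     cbind(x = c(1, 1, 1, 0, 0, 0)))
  fit <- fit_cox(d)
  expect_false(fit$converged)
  expect_true(fit$monotone)
  expect_error(wald_interval(fit), "converge")
})

test_that("Wald intervals follow normal-quantile arithmetic and widen with Bonferroni", {
  ch <- generate_cohort(cohort_config(n_patients = 300), seed = 3)
  d <- survival_data(ch$time, ch$event, cbind(apache2 = ch$apache2))
  fit <- fit_cox(d)
  wi <- wald_interval(fit, 1, alpha = 0.05)
  z <- qnorm(0.975)
  expect_equal(unname(wi["hr"]), exp(unname(fit$beta[1])))
  expect_equal(unname(wi["lower"]), exp(fit$beta[[1]] - z * fit$se[[1]]))
  expect_equal(unname(wi["upper"]), exp(fit$beta[[1]] + z * fit$se[[1]]))
  wb <- wald_interval(fit, 1, alpha = 0.05 / 31)
  expect_lt(wb["lower"], wi["lower"])
  expect_gt(wb["upper"], wi["upper"])
})

test_that("score test equals the log-rank chi-square for binary covariates", {
  # mirrored groups carry no information
  d0 <- survival_data(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                      cbind(g = c(0, 0, 0, 1, 1, 1)))
  expect_lt(score_test(d0)$statistic, 1e-12)
  # one subject per group: hand evaluation gives U = 1/2, I = 1/4, stat = 1
  d1 <- survival_data(c(1, 2), c(1, 1), cbind(g = c(1, 0)))
  expect_equal(score_test(d1)$statistic, 1)
  expect_equal(logrank_test(c(1, 2), c(1, 1), c(1, 0))$statistic, 1)
  # random two-group datasets without tied event times: agreement to 1e-8
  # (with tied deaths the log-rank variance carries a hypergeometric
  # correction the score information does not, so the identity is exact
  # only on tie-free event times)
  set.seed(99)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    tm <- round(rexp(n) * 20, 6) + 0.01
    ev <- pmax(rbinom(n, 1, 0.5), c(1, rep(0, n - 1)))
    g <- c(0, 1, rbinom(n - 2, 1, 0.5))
    st <- score_test(survival_data(tm, ev, cbind(g = g)), ties = "breslow")
    lr <- logrank_test(tm, ev, g)
    expect_equal(st$statistic, lr$statistic, tolerance = 1e-8)
  }
})

test_that("the Breslow baseline reduces to Nelson-Aalen at beta = 0", {
  d <- survival_data(c(1, 2, 3), c(1, 1, 1), cbind(x = c(1, 0, 1)))
  bh <- breslow_baseline(NULL, d, beta = 0)
  expect_equal(bh$cumhaz, cumsum(c(1 / 3, 1 / 2, 1)))
  d2 <- survival_data(c(2, 3, 3, 5, 8), c(0, 0, 1, 0, 0), cbind(x = 1:5 / 5))
  bh2 <- breslow_baseline(NULL, d2, beta = 0)
  expect_equal(bh2$cumhaz, 1 / 4)  # single event among the 4 still at risk
})

test_that("model-based survival predictions are proper survival functions", {
  set.seed(123)
  for (i in 1:5) {
    ch <- generate_cohort(cohort_config(n_patients = 120), seed = 200 + i)
    d <- survival_data(ch$time, ch$event, cbind(bmi = ch$bmi, ap = ch$apache2))
    fit <- fit_cox(d)
    bh <- breslow_baseline(fit, d)
    expect_true(all(diff(bh$cumhaz) >= 0))
    s <- exp(-outer(bh$cumhaz, exp(as.vector(d$X %*% fit$beta))))
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(apply(s, 2, function(col) all(diff(col) <= 0))))
  }
})

test_that("dfbeta influence values match the reference implementation", {
  skip_if_not_installed("survival")
  ch <- generate_cohort(cohort_config(n_patients = 250), seed = 9)
  d <- survival_data(ch$time, ch$event, cbind(bmi = ch$bmi, ap = ch$apache2))
  fit <- fit_cox(d, ties = "breslow")
  D <- cox_dfbeta(fit, d)
  ref <- survival::coxph(survival::Surv(time, event) ~ bmi + apache2,
                         data = ch, ties = "breslow")
  Dref <- stats::residuals(ref, type = "dfbeta")
  expect_equal(unname(D), unname(Dref), tolerance = 1e-8)
  # score residuals sum to the (vanishing) score at the MLE
  expect_lt(max(abs(colSums(D))), 1e-6)
})

test_that("a known single-covariate log hazard ratio is recovered on average", {
  # exponential truth, log-HR 0.5, independent exponential censoring
  est <- vapply(1:200, function(s) {
    set.seed(3000 + s)
    n <- 2000
    x <- rnorm(n)
    td <- rexp(n) / (0.02 * exp(0.5 * x))
    tc <- rexp(n) / 0.02
    tm <- pmin(td, tc)
    ev <- as.integer(td <= tc)
    unname(fit_cox(survival_data(tm, ev, cbind(x = x)))$beta)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.05)
})
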