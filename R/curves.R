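#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate with Greenwood standard errors, computed with
#' \pkg{survival}'s `survfit` machinery and returned as a tidy table defined
#' at the observed event times (censored-only times contribute to the risk
#' set but carry no step).
#'
#' @param time follow-up times (> 0).
#' @param event 0/1 event indicators.
#' @param label optional stratum label stored on the curve.
#' @return a `data.frame` of class `survival_curve` with columns `time`,
#'   `at_risk`, `events`, `survival`, `greenwood_se`, `label`.
#' @export
km_estimate <- function(time, event, label = "all") {
  if (length(time) == 0) stop("km_estimate: empty input", call. = FALSE)
  if (any(time <= 0)) stop("km_estimate: times must be > 0", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, se.fit = TRUE)
  keep <- fit$n.event > 0
  s <- fit$surv[keep]
  # survfit std.err is the SE of the cumulative hazard; Greenwood SE of S
  gse <- s * fit$std.err[keep]
  gse[s == 0] <- 0
  structure(data.frame(time = fit$time[keep],
                       at_risk = fit$n.risk[keep],
                       events = fit$n.event[keep],
                       survival = s,
                       greenwood_se = gse,
                       label = label,
                       stringsAsFactors = FALSE),
            class = c("survival_curve", "data.frame"))
}

#' Log-rank test for equality of survival across groups
#'
#' Standard (rho = 0) log-rank chi-square via `survival::survdiff`. For two
#' groups it is algebraically identical to the Breslow score test of the
#' group indicator in a Cox model ([score_test()]), which the test-suite
#' exploits as a cross-module oracle.
#'
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @param group group labels (>= 2 distinct values).
#' @return a list with `statistic`, `df` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2)
    stop("logrank_test: at least two groups are required", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Covariate-adjusted survival curves by strata (corrected group prognosis)
#'
#' Fits the stratified adjusted Cox model of [group_cox()], recovers the
#' Breslow baseline hazard, and for each stratum averages the Cox-predicted
#' individual survival curves over the whole cohort with the group
#' indicators forced to that stratum and each subject's adjustment
#' covariates left at their observed values. With all fitted coefficients
#' zero every stratum reduces to `exp(-Lambda0(t))`.
#'
#' @inheritParams group_cox
#' @return a `data.frame` of class `adjusted_curves` with columns `stratum`,
#'   `time`, `survival`; the underlying `group_cox_fit` is attached as
#'   attribute `fit`.
#' @export
adjusted_curves <- function(cohort, bounds = c(20, 24, 35),
                            adjust_for = c("apache2", "hba1c"),
                            covariate = "bmi",
                            ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  gc_fit <- group_cox(cohort, bounds = bounds, adjust_for = adjust_for,
                      covariate = covariate, ties = ties)
  if (!gc_fit$fit$converged)
    stop("adjusted_curves: stratified Cox fit did not converge", call. = FALSE)
  k <- length(bounds) + 1L
  Z <- sapply(2:k, function(gi) as.integer(gc_fit$membership == gi))
  X <- cbind(Z, as.matrix(cohort[, adjust_for, drop = FALSE]))
  d <- survival_data(cohort$time, cohort$event, X)
  bh <- breslow_baseline(gc_fit$fit, d)
  H0 <- bh$cumhaz
  beta <- gc_fit$fit$beta
  b_grp <- c(0, beta[seq_len(k - 1L)])
  lp_adj <- as.vector(as.matrix(cohort[, adjust_for, drop = FALSE]) %*%
                        beta[k:length(beta)])
  labels <- group_labels(bounds, covariate)
  out <- do.call(rbind, lapply(seq_len(k), function(gi) {
    risk <- exp(b_grp[gi] + lp_adj)              # per-subject, stratum forced
    surv <- vapply(H0, function(h) mean(exp(-h * risk)), numeric(1))
    data.frame(stratum = labels[gi], time = bh$time, survival = surv,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("adjusted_curves", "data.frame"), fit = gc_fit)
}
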