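#' Specification of a dichotomization cutpoint scan
#'
#' The scan walks an inclusive grid of cutoffs (e.g. BMI 20 to 35 by 0.5,
#' giving 31 tested cutpoints), splits the cohort at each cutoff, and fits an
#' adjusted Cox model to the group indicator. `direction` fixes which side of
#' the cutoff carries the indicator: `"risk-below"` codes 1 for subjects with
#' covariate `< cutoff` (so HR > 1 means higher mortality for the low side,
#' the BMI convention), `"risk-above"` codes 1 for `>= cutoff` (the HbA1c
#' convention).
#'
#' @param covariate column name of the scanned covariate (`"bmi"` or
#'   `"hba1c"` in the standard cohort schema).
#' @param grid_lo,grid_hi scan range in covariate units (both endpoints are
#'   tested).
#' @param step grid increment (default 0.5).
#' @param direction `"risk-below"` or `"risk-above"`.
#' @param adjust_for character vector of adjustment covariate columns
#'   (default `"apache2"`).
#' @param min_events_per_group cutoffs leaving fewer events than this on
#'   either side are flagged unusable and excluded from smoothing
#'   (default 5).
#' @param alpha two-sided level for the simultaneous band (default 0.05).
#' @return an object of class `scan_spec`.
#' @export
scan_spec <- function(covariate, grid_lo, grid_hi, step = 0.5,
                      direction = c("risk-below", "risk-above"),
                      adjust_for = "apache2",
                      min_events_per_group = 5L, alpha = 0.05) {
  direction <- match.arg(direction)
  stopifnot(is.character(covariate), length(covariate) == 1L,
            is.numeric(grid_lo), is.numeric(grid_hi), grid_lo < grid_hi,
            is.numeric(step), step > 0,
            min_events_per_group >= 0, alpha > 0, alpha < 1)
  grid <- seq(grid_lo, grid_hi, by = step)
  if (length(grid) < 4L)
    stop("scan_spec: the cutoff grid must contain at least 4 points ",
         "(the spline needs 4 knots)", call. = FALSE)
  structure(list(covariate = covariate, grid_lo = grid_lo, grid_hi = grid_hi,
                 step = step, direction = direction, adjust_for = adjust_for,
                 min_events_per_group = as.integer(min_events_per_group),
                 alpha = alpha, grid = grid),
            class = "scan_spec")
}

#' Dichotomize a covariate at a cutoff
#'
#' @param x numeric covariate values.
#' @param cutoff cut point in covariate units.
#' @param direction see [scan_spec()].
#' @return integer 0/1 indicator vector. A cut producing an all-0 or all-1
#'   indicator is degenerate and signalled as an error.
#' @export
dichotomize <- function(x, cutoff, direction = c("risk-below", "risk-above")) {
  direction <- match.arg(direction)
  z <- if (direction == "risk-below") as.integer(x < cutoff) else
    as.integer(x >= cutoff)
  if (all(z == 0L) || all(z == 1L))
    stop(sprintf("degenerate cut: cutoff %g leaves a single group", cutoff),
         call. = FALSE)
  z
}

#' Run a dichotomization cutpoint scan of adjusted hazard ratios
#'
#' For every cutoff on the grid the cohort is split in two, and a Cox model
#' with the group indicator plus the adjustment covariates is fit by maximum
#' partial likelihood. Each cutoff yields the adjusted log hazard ratio of
#' the indicator with its standard error and group/event counts. Cutoffs
#' whose fit does not converge (separation at extreme cuts), whose cut is
#' degenerate, or which leave fewer than `min_events_per_group` events on
#' either side are flagged `usable = FALSE` and excluded from smoothing.
#'
#' @param cohort a cohort `data.frame` (see [generate_cohort()] for the
#'   schema; only `time`, `event`, the scanned covariate and the adjustment
#'   columns are required).
#' @param spec a [scan_spec()].
#' @param ties tie-handling method passed to the Cox fits.
#' @return a `data.frame` of class `scan_points` with one row per attempted
#'   cutoff: `cutoff`, `loghr`, `se`, `hr`, `n_low`, `n_high`, `events_low`,
#'   `events_high`, `converged`, `usable`.
#' @export
run_scan <- function(cohort, spec, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(inherits(spec, "scan_spec"))
  need <- c("time", "event", spec$covariate, spec$adjust_for)
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0)
    stop("run_scan: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- cohort[[spec$covariate]]
  A <- as.matrix(cohort[, spec$adjust_for, drop = FALSE])
  storage.mode(A) <- "double"
  time <- cohort$time
  event <- as.integer(cohort$event)

  # sort once; every cutoff reuses the same risk-set bookkeeping
  ord <- order(time)
  x_s <- x[ord]
  A_s <- A[ord, , drop = FALSE]
  base_prep <- cox_prep(time, event, cbind(ind = 0, A))

  n <- length(time)
  dfb <- matrix(NA_real_, n, length(spec$grid))  # influence of the indicator
  one <- function(i) {
    cutoff <- spec$grid[i]
    out <- data.frame(cutoff = cutoff, loghr = NA_real_, se = NA_real_,
                      hr = NA_real_, n_low = sum(x < cutoff),
                      n_high = sum(x >= cutoff),
                      events_low = sum(event[x < cutoff]),
                      events_high = sum(event[x >= cutoff]),
                      converged = FALSE, usable = FALSE)
    z <- tryCatch(dichotomize(x_s, cutoff, spec$direction),
                  error = function(e) NULL)
    if (is.null(z)) return(out)
    prep <- base_prep
    prep$X[, 1] <- z
    fit <- tryCatch(cox_newton(prep, ties = ties), error = function(e) NULL)
    if (is.null(fit)) return(out)
    out$loghr <- fit$beta[1]
    out$se <- sqrt(fit$cov[1, 1])
    out$hr <- exp(fit$beta[1])
    out$converged <- fit$converged
    out$usable <- fit$converged &&
      min(out$events_low, out$events_high) >= spec$min_events_per_group &&
      is.finite(out$se)
    if (out$usable)
      dfb[, i] <<- (cox_score_residuals_prep(prep, fit$beta) %*% fit$cov)[, 1]
    out
  }
  pts <- do.call(rbind, lapply(seq_along(spec$grid), one))
  rownames(pts) <- NULL
  if (sum(pts$usable) < 4L)
    stop("scan failure: fewer than 4 usable cutoffs", call. = FALSE)
  structure(pts, class = c("scan_points", "data.frame"),
            spec = spec, n = nrow(cohort), n_events = sum(event),
            dfbeta = dfb)
}

# Harrell-style restricted cubic spline design (4 knots): intercept + ns basis
rcs_knots <- function(cutoffs) {
  stats::quantile(cutoffs, probs = c(0.05, 0.35, 0.65, 0.95),
                  names = FALSE, type = 7)
}

rcs_basis <- function(x, knots) {
  cbind(1, splines::ns(x, knots = knots[2:3], Boundary.knots = knots[c(1, 4)]))
}

#' Smooth a cutpoint scan with a four-knot restricted cubic spline
#'
#' The usable scan points' log hazard ratios are smoothed against the cutoff
#' by weighted least squares on a restricted (natural) cubic spline basis
#' with four knots placed at the 5th/35th/65th/95th percentiles of the usable
#' cutoffs; weights are the inverse variances `1/se^2`. The simultaneous band
#' is `exp(fitted +/- z * SE_fit)` with `z = qnorm(1 - alpha / (2 m))`, where
#' `m` is the number of usable (tested) cutoffs — a Bonferroni correction
#' over the tested cutpoints.
#'
#' Because every scan point is computed on the same cohort, points at
#' neighbouring cutoffs are strongly positively correlated, and a band that
#' treats them as independent observations is badly anti-conservative. The
#' default `se_method = "robust"` therefore propagates an influence-function
#' (infinitesimal-jackknife) estimate of the full between-cutoff covariance,
#' `Cov(b_c, b_c') = sum_i dfbeta_c(i) dfbeta_c'(i)` (see [cox_dfbeta()]),
#' through the spline's linear smoother. `se_method = "independence"` gives
#' the naive weighted-least-squares covariance `(B'WB)^-1` with dispersion
#' fixed at 1; it is retained for comparison and for hand-constructed scan
#' tables without influence information.
#'
#' @param points a [run_scan()] result.
#' @param n_eval number of evaluation points spanning the scan range
#'   (default 201).
#' @param se_method `"robust"` (default; falls back to `"independence"`
#'   with a warning when `points` carries no influence information) or
#'   `"independence"`.
#' @return a `data.frame` of class `spline_band` with columns `cutoff`,
#'   `loghr_fit`, `se_fit`, `hr`, `lower`, `upper`; attributes `m`, `knots`,
#'   `alpha`, `zcrit` and the originating `spec`.
#' @export
smooth_scan <- function(points, n_eval = 201L,
                        se_method = c("robust", "independence")) {
  stopifnot(inherits(points, "scan_points"))
  se_method <- match.arg(se_method)
  spec <- attr(points, "spec")
  dfb <- attr(points, "dfbeta")
  usable <- points$usable
  use <- points[usable, , drop = FALSE]
  m <- nrow(use)
  if (m < 4L)
    stop("smooth_scan: at least 4 usable scan points are required", call. = FALSE)
  if (se_method == "robust" && is.null(dfb)) {
    warning("smooth_scan: no influence information on 'points'; ",
            "falling back to se_method = \"independence\"")
    se_method <- "independence"
  }
  knots <- rcs_knots(use$cutoff)
  if (anyDuplicated(knots))
    stop("smooth_scan: coincident spline knots (singular design)", call. = FALSE)
  B <- rcs_basis(use$cutoff, knots)
  w <- 1 / use$se^2
  XtWX <- crossprod(B, w * B)
  coefs <- tryCatch(solve(XtWX, crossprod(B, w * use$loghr)),
                    error = function(e)
                      stop("smooth_scan: singular spline design", call. = FALSE))
  grid <- seq(spec$grid_lo, spec$grid_hi, length.out = n_eval)
  Bg <- rcs_basis(grid, knots)
  fit <- as.vector(Bg %*% coefs)
  if (se_method == "robust") {
    Sigma <- crossprod(dfb[, usable, drop = FALSE])   # m x m between-cutoff cov
    Hg <- Bg %*% solve(XtWX, t(B * w))                # eval-grid smoother matrix
    se_fit <- sqrt(rowSums((Hg %*% Sigma) * Hg))
  } else {
    V <- solve(XtWX)                  # dispersion fixed at 1: weights = 1/Var
    se_fit <- sqrt(rowSums((Bg %*% V) * Bg))
  }
  zcrit <- stats::qnorm(1 - spec$alpha / (2 * m))
  structure(data.frame(cutoff = grid, loghr_fit = fit, se_fit = se_fit,
                       hr = exp(fit),
                       lower = exp(fit - zcrit * se_fit),
                       upper = exp(fit + zcrit * se_fit)),
            class = c("spline_band", "data.frame"),
            m = m, knots = knots, alpha = spec$alpha, zcrit = zcrit,
            spec = spec, coefs = as.vector(coefs))
}

#' Locate covariate ranges where the simultaneous band excludes HR = 1
#'
#' Scans the evaluation grid of a [smooth_scan()] band for maximal
#' sub-intervals where the lower band exceeds 1 (side `"risk"`) or the upper
#' band falls below 1 (side `"protection"`). The headline threshold is the
#' smallest boundary of the first risk interval — e.g. an HbA1c of 9.3% when
#' the band first clears 1 there.
#'
#' @param band a [smooth_scan()] result.
#' @return an object of class `threshold_call`: a list with `intervals` (a
#'   `data.frame` with `from`, `to`, `side`) and `headline` (numeric, `NA` if
#'   the band covers 1 everywhere).
#' @export
detect_threshold <- function(band) {
  stopifnot(inherits(band, "spline_band"))
  runs_of <- function(flag, side) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values)
    if (length(k) == 0) return(NULL)
    data.frame(from = band$cutoff[starts[k]], to = band$cutoff[ends[k]],
               side = side, stringsAsFactors = FALSE)
  }
  intervals <- rbind(runs_of(band$lower > 1, "risk"),
                     runs_of(band$upper < 1, "protection"))
  if (is.null(intervals))
    intervals <- data.frame(from = numeric(0), to = numeric(0),
                            side = character(0), stringsAsFactors = FALSE)
  intervals <- intervals[order(intervals$from), , drop = FALSE]
  rownames(intervals) <- NULL
  risk <- intervals[intervals$side == "risk", , drop = FALSE]
  headline <- if (nrow(risk) > 0) min(risk$from[1], risk$to[1]) else NA_real_
  structure(list(intervals = intervals, headline = headline),
            class = "threshold_call")
}

#' @export
print.threshold_call <- function(x, ...) {
  if (nrow(x$intervals) == 0) {
    cat("threshold call: band covers HR = 1 everywhere (no call)\n")
  } else {
    cat("threshold call: band excludes HR = 1 on\n")
    for (i in seq_len(nrow(x$intervals)))
      cat(sprintf("  [%.3g, %.3g]  (%s)\n", x$intervals$from[i],
                  x$intervals$to[i], x$intervals$side[i]))
    if (!is.na(x$headline))
      cat(sprintf("  headline threshold: %.3g\n", x$headline))
  }
  invisible(x)
}

#' Adjusted Cox model over covariate strata
#'
#' Cuts a continuous covariate into `length(bounds) + 1` lower-inclusive
#' groups (e.g. BMI bounds 20/24/35 give <20, 20-23.9, 24-34.9, >=35), fits
#' a Cox model with indicator terms for groups 2..k (the first group is the
#' reference) plus adjustment covariates, and reports per-group hazard
#' ratios against the reference with Wald confidence intervals and p-values.
#'
#' @param cohort a cohort `data.frame`.
#' @param bounds increasing interior cut points.
#' @param adjust_for adjustment columns (default APACHE II and HbA1c, the
#'   adjustment set of the stratified mortality comparison).
#' @param covariate stratified column (default `"bmi"`).
#' @param alpha level of the per-group Wald intervals.
#' @param ties tie-handling method.
#' @return an object of class `group_cox_fit`: list with the underlying
#'   `fit` ([fit_cox()]), `groups` (a per-group `data.frame` with `n`,
#'   `events`, `hr`, `lower`, `upper`, `p`) and `bounds`.
#' @export
group_cox <- function(cohort, bounds = c(20, 24, 35),
                      adjust_for = c("apache2", "hba1c"),
                      covariate = "bmi", alpha = 0.05,
                      ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(is.numeric(bounds), !is.unsorted(bounds, strictly = TRUE))
  x <- cohort[[covariate]]
  if (is.null(x)) stop("group_cox: missing column ", covariate, call. = FALSE)
  g <- findInterval(x, bounds) + 1L   # lower-inclusive bins
  k <- length(bounds) + 1L
  labels <- group_labels(bounds, covariate)
  for (gi in seq_len(k)) {
    if (sum(g == gi) == 0)
      stop("group_cox: empty stratum ", labels[gi], call. = FALSE)
    if (sum(cohort$event[g == gi]) == 0)
      stop("group_cox: no events in stratum ", labels[gi], call. = FALSE)
  }
  Z <- sapply(2:k, function(gi) as.integer(g == gi))
  colnames(Z) <- paste0("group", 2:k)
  X <- cbind(Z, as.matrix(cohort[, adjust_for, drop = FALSE]))
  d <- survival_data(cohort$time, cohort$event, X)
  fit <- fit_cox(d, ties = ties)
  z <- stats::qnorm(1 - alpha / 2)
  idx <- seq_len(k - 1L)
  b <- fit$beta[idx]
  s <- fit$se[idx]
  groups <- data.frame(
    group = labels,
    n = as.vector(table(factor(g, levels = seq_len(k)))),
    events = as.vector(tapply(cohort$event, factor(g, levels = seq_len(k)), sum)),
    hr = c(1, exp(b)),
    lower = c(NA, exp(b - z * s)),
    upper = c(NA, exp(b + z * s)),
    p = c(NA, 2 * stats::pnorm(-abs(b / s))),
    stringsAsFactors = FALSE
  )
  structure(list(fit = fit, groups = groups, bounds = bounds,
                 covariate = covariate, adjust_for = adjust_for,
                 membership = g),
            class = "group_cox_fit")
}

group_labels <- function(bounds, covariate) {
  k <- length(bounds) + 1L
  lab <- character(k)
  lab[1] <- sprintf("%s<%g", covariate, bounds[1])
  if (k > 2)
    for (gi in 2:(k - 1L))
      lab[gi] <- sprintf("%s %g-%g", covariate, bounds[gi - 1L], bounds[gi])
  lab[k] <- sprintf("%s>=%g", covariate, bounds[k - 1L])
  lab
}

#' @export
print.group_cox_fit <- function(x, ...) {
  cat(sprintf("Stratified Cox model on %s (adjusted for %s)\n",
              x$covariate, paste(x$adjust_for, collapse = ", ")))
  tab <- x$groups
  tab$hr <- round(tab$hr, 3)
  tab$lower <- round(tab$lower, 3)
  tab$upper <- round(tab$upper, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
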