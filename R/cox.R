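#' Construct a survival dataset
#'
#' Bundles follow-up times, event indicators and a covariate matrix after
#' validation: strictly positive times, at least one event, binary event
#' codes, no missing values, and no constant covariate column (a constant
#' column makes the partial-likelihood design degenerate).
#'
#' @param time numeric vector of follow-up times (days, > 0).
#' @param event 0/1 vector; 1 = in-hospital death.
#' @param X covariate matrix or data.frame (subjects x p) with column names.
#' @return an object of class `survival_data`.
#' @export
survival_data <- function(time, event, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  n <- length(time)
  if (length(event) != n || nrow(X) != n)
    stop("survival_data: time, event and X must have matching lengths", call. = FALSE)
  if (anyNA(time) || anyNA(event) || anyNA(X))
    stop("survival_data: missing values are not allowed", call. = FALSE)
  if (any(time <= 0)) stop("survival_data: all times must be > 0", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("survival_data: event must be 0/1", call. = FALSE)
  if (sum(event) < 1) stop("survival_data: at least one event is required", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate design: constant covariate column '",
         colnames(X)[which(sds == 0)[1]], "'", call. = FALSE)
  structure(list(time = as.numeric(time), event = as.integer(event), X = X),
            class = "survival_data")
}

# sort once by time; precompute risk-set bookkeeping reused across evaluations
cox_prep <- function(time, event, X) {
  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  X <- X[ord, , drop = FALSE]
  first <- match(time, time)          # first row of each tied time block
  ev <- which(event == 1L)
  ev_time <- time[ev]
  grp <- match(ev_time, ev_time)      # tied-event groups (by death time)
  d <- tabulate(grp, nbins = length(ev))
  list(time = time, event = event, X = X, first = first,
       ev = ev, ev_grp = grp, ev_d = d,
       has_ties = any(d[unique(grp)] > 1L))
}

suffix_sum <- function(v) rev(cumsum(rev(v)))

# partial log-likelihood, score vector and observed information at beta
cox_eval <- function(prep, beta, ties = "efron") {
  X <- prep$X
  p <- ncol(X)
  n <- nrow(X)
  eta <- as.vector(X %*% beta)
  w <- exp(eta)
  S0 <- suffix_sum(w)
  S1 <- matrix(0, n, p)
  for (j in seq_len(p)) S1[, j] <- suffix_sum(w * X[, j])
  np <- p * (p + 1L) / 2L
  S2 <- matrix(0, n, np)
  jk <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  for (m in seq_len(np))
    S2[, m] <- suffix_sum(w * X[, jk[m, 1]] * X[, jk[m, 2]])
  unpack <- function(v) { # packed upper triangle -> symmetric p x p
    M <- matrix(0, p, p)
    M[cbind(jk[, 1], jk[, 2])] <- v
    M[cbind(jk[, 2], jk[, 1])] <- v
    M
  }
  ev <- prep$ev
  r <- prep$first[ev]
  loglik <- sum(eta[ev])
  U <- colSums(X[ev, , drop = FALSE])
  I <- matrix(0, p, p)

  breslow_part <- function(r) {
    d0 <- S0[r]
    loglik <<- loglik - sum(log(d0))
    m1 <- S1[r, , drop = FALSE] / d0
    U <<- U - colSums(m1)
    for (m in seq_len(np)) {
      j <- jk[m, 1]; k <- jk[m, 2]
      val <- sum(S2[r, m] / d0 - m1[, j] * m1[, k])
      I[j, k] <<- I[j, k] + val
      if (j != k) I[k, j] <<- I[k, j] + val
    }
  }

  if (ties == "breslow" || !prep$has_ties) {
    breslow_part(r)
  } else {
    # Efron: vectorize the untied deaths, loop only over tied groups
    tied <- prep$ev_d[prep$ev_grp] > 1L
    if (any(!tied)) breslow_part(r[!tied])
    for (g in unique(prep$ev_grp[tied])) {
      idx <- ev[prep$ev_grp == g]
      ri <- prep$first[idx[1]]
      dg <- length(idx)
      wD <- w[idx]
      D0 <- sum(wD)
      D1 <- colSums(wD * X[idx, , drop = FALSE])
      D2v <- vapply(seq_len(np), function(m)
        sum(wD * X[idx, jk[m, 1]] * X[idx, jk[m, 2]]), numeric(1))
      for (k0 in seq_len(dg) - 1L) {
        phi <- k0 / dg
        den0 <- S0[ri] - phi * D0
        m1 <- (S1[ri, ] - phi * D1) / den0
        loglik <- loglik - log(den0)
        U <- U - m1
        M2 <- unpack((S2[ri, ] - phi * D2v) / den0)
        I <- I + M2 - tcrossprod(m1)
      }
    }
  }
  list(loglik = loglik, U = U, I = I)
}

#' Cox partial log-likelihood
#'
#' Evaluates the Breslow- or Efron-corrected partial log-likelihood of a
#' proportional-hazards model at a given coefficient vector. At `beta = 0`
#' the two tie corrections agree.
#'
#' @param data a [survival_data()] object.
#' @param beta numeric coefficient vector (length = number of covariates).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return the partial log-likelihood (a scalar).
#' @export
partial_loglik <- function(data, beta, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(inherits(data, "survival_data"))
  if (anyNA(beta) || any(!is.finite(beta)))
    stop("partial_loglik: beta must be finite", call. = FALSE)
  if (length(beta) != ncol(data$X))
    stop("partial_loglik: beta has wrong length", call. = FALSE)
  prep <- cox_prep(data$time, data$event, data$X)
  cox_eval(prep, beta, ties)$loglik
}

# Newton-Raphson with step-halving on a prepared dataset
cox_newton <- function(prep, ties = "efron", max_iter = 50L, tol = 1e-8,
                       max_halvings = 10L) {
  p <- ncol(prep$X)
  beta <- numeric(p)
  cur <- cox_eval(prep, beta, ties)
  loglik_null <- cur$loglik
  converged <- FALSE
  monotone <- FALSE
  iter <- 0L
  repeat {
    if (max(abs(cur$U)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    iter <- iter + 1L
    step <- tryCatch(solve(cur$I, cur$U), error = function(e)
      stop("degenerate design: singular information matrix", call. = FALSE))
    new_beta <- beta + step
    new <- cox_eval(prep, new_beta, ties)
    h <- 0L
    while ((!is.finite(new$loglik) || new$loglik < cur$loglik) && h < max_halvings) {
      h <- h + 1L
      new_beta <- beta + step / 2^h
      new <- cox_eval(prep, new_beta, ties)
    }
    rel_change <- abs(new$loglik - cur$loglik) / max(1, abs(cur$loglik))
    beta <- new_beta
    cur <- new
    if (any(abs(beta) > 15)) { monotone <- TRUE; break }
    if (rel_change < tol) { converged <- TRUE; break }
  }
  cov <- tryCatch(solve(cur$I), error = function(e) matrix(NA_real_, p, p))
  cov <- (cov + t(cov)) / 2
  list(beta = beta, cov = cov, loglik = cur$loglik, loglik_null = loglik_null,
       U = cur$U, I = cur$I, converged = converged && !monotone,
       monotone = monotone, n_iter = iter)
}

#' Fit a Cox proportional-hazards model by maximum partial likelihood
#'
#' Newton-Raphson from `beta = 0` with step-halving; convergence is declared
#' when the score sup-norm falls below `tol` (or the relative log-likelihood
#' change vanishes). A coefficient drifting beyond |beta| > 15 is flagged as
#' monotone likelihood (separation) and reported as non-convergence rather
#' than returned silently.
#'
#' @inheritParams partial_loglik
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the score sup-norm.
#' @return an object of class `cox_fit` with elements `beta`, `se`, `cov`,
#'   `loglik_null`, `loglik`, `n`, `n_events`, `ties`, `converged`,
#'   `monotone`, `n_iter`.
#' @examples
#' d <- survival_data(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1),
#'                    X = cbind(x = c(1, 0, 1, 0)))
#' fit_cox(d)
#' @export
fit_cox <- function(data, ties = c("efron", "breslow"), max_iter = 50L,
                    tol = 1e-8) {
  ties <- match.arg(ties)
  stopifnot(inherits(data, "survival_data"))
  prep <- cox_prep(data$time, data$event, data$X)
  res <- cox_newton(prep, ties, max_iter, tol)
  se <- sqrt(diag(res$cov))
  names(res$beta) <- names(se) <- colnames(data$X)
  dimnames(res$cov) <- list(colnames(data$X), colnames(data$X))
  structure(list(
    beta = res$beta, se = se, cov = res$cov,
    loglik_null = res$loglik_null, loglik = res$loglik,
    n = length(data$time), n_events = sum(data$event),
    ties = ties, converged = res$converged, monotone = res$monotone,
    n_iter = res$n_iter
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  if (!x$converged) {
    cat(if (x$monotone)
      "  NOT CONVERGED: monotone likelihood (separation) detected\n"
      else "  NOT CONVERGED\n")
  }
  tab <- data.frame(coef = x$beta, `exp(coef)` = exp(x$beta), se = x$se,
                    z = x$beta / x$se,
                    p = 2 * stats::pnorm(-abs(x$beta / x$se)),
                    check.names = FALSE)
  print(round(tab, 4))
  cat(sprintf("  partial log-likelihood: %0.4f (null %0.4f), %d iterations\n",
              x$loglik, x$loglik_null, x$n_iter))
  invisible(x)
}

#' Wald confidence interval for a hazard ratio
#'
#' @param fit a converged [fit_cox()] object.
#' @param j covariate index or name.
#' @param alpha two-sided level (default 0.05); use `alpha / m` for a
#'   Bonferroni correction over m tests.
#' @return named numeric vector `(hr, lower, upper)`.
#' @export
wald_interval <- function(fit, j = 1L, alpha = 0.05) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged)
    stop("wald_interval: fit did not converge", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  b <- fit$beta[[j]]
  s <- fit$se[[j]]
  c(hr = exp(b), lower = exp(b - z * s), upper = exp(b + z * s))
}

#' Score (Rao) test of no covariate effect
#'
#' Chi-square score test of `beta = 0`. For a single binary covariate with
#' Breslow tie handling and no tied event times this is algebraically the
#' classic log-rank chi-square, which is exploited as a cross-module oracle
#' against [logrank_test()]. (With tied deaths the log-rank variance carries
#' a hypergeometric finite correction the score information does not, and
#' the two differ slightly.)
#'
#' @inheritParams partial_loglik
#' @return a list with `statistic`, `df` and `p`.
#' @export
score_test <- function(data, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(inherits(data, "survival_data"))
  prep <- cox_prep(data$time, data$event, data$X)
  ev <- cox_eval(prep, numeric(ncol(data$X)), ties)
  stat <- drop(crossprod(ev$U, solve(ev$I, ev$U)))
  df <- ncol(data$X)
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Breslow estimate of the cumulative baseline hazard
#'
#' Nondecreasing step function with jumps `d_t / sum(exp(x'beta))` over the
#' risk set at each distinct event time. With `beta = 0` it reduces to the
#' Nelson-Aalen estimator.
#'
#' @param fit a converged [fit_cox()] object (or any object with a `beta`
#'   component matching `data`).
#' @param data the [survival_data()] the model was fit to.
#' @param beta optional coefficient vector overriding `fit$beta`.
#' @return a `data.frame` with columns `time`, `n_events`, `cumhaz`, of class
#'   `baseline_hazard`.
#' @export
breslow_baseline <- function(fit, data, beta = NULL) {
  stopifnot(inherits(data, "survival_data"))
  if (is.null(beta)) {
    stopifnot(inherits(fit, "cox_fit"))
    if (!fit$converged)
      stop("breslow_baseline: fit did not converge", call. = FALSE)
    beta <- fit$beta
  }
  prep <- cox_prep(data$time, data$event, data$X)
  w <- exp(as.vector(prep$X %*% beta))
  S0 <- suffix_sum(w)
  ev <- prep$ev
  r <- prep$first[ev]
  evt <- prep$time[ev]            # ascending
  keep <- !duplicated(evt)
  ut <- evt[keep]
  d <- tabulate(match(evt, ut))
  s0 <- S0[r][keep]
  structure(data.frame(time = ut, n_events = d, cumhaz = cumsum(d / s0)),
            class = c("baseline_hazard", "data.frame"))
}

# step-function evaluation of a baseline cumulative hazard
cumhaz_at <- function(bh, t) {
  f <- stats::stepfun(bh$time, c(0, bh$cumhaz))
  f(t)
}

# Breslow-form score residuals at beta, on a prepared (sorted) dataset;
# returns an n x p matrix in the prep's (time-sorted) row order
cox_score_residuals_prep <- function(prep, beta) {
  X <- prep$X
  p <- ncol(X)
  n <- nrow(X)
  w <- exp(as.vector(X %*% beta))
  S0 <- suffix_sum(w)
  ev <- prep$ev
  r <- prep$first[ev]
  evt <- prep$time[ev]
  keep <- !duplicated(evt)
  ut <- evt[keep]
  d <- tabulate(match(evt, ut))
  s0 <- S0[r][keep]
  S1u <- matrix(0, length(ut), p)
  for (j in seq_len(p)) S1u[, j] <- suffix_sum(w * X[, j])[r][keep]
  xbar <- S1u / s0
  A0 <- cumsum(d / s0)                           # Breslow cumulative hazard
  A1 <- apply(d * S1u / s0^2, 2, cumsum)
  if (p == 1L) A1 <- matrix(A1, ncol = 1L)
  pos <- findInterval(prep$time, ut)             # last event time <= t_i
  A0i <- c(0, A0)[pos + 1L]
  A1i <- rbind(0, A1)[pos + 1L, , drop = FALSE]
  L <- -w * (X * A0i - A1i)
  di <- prep$event == 1L
  L[di, ] <- L[di, ] + X[di, , drop = FALSE] -
    xbar[match(prep$time[di], ut), , drop = FALSE]
  L
}

#' Per-subject dfbeta (influence) values of a Cox fit
#'
#' Approximate change in each coefficient from deleting one subject:
#' `I^-1 L_i`, with `L_i` the Breslow-form score residual at the fitted
#' coefficients. Their cross-products give a robust (infinitesimal-jackknife)
#' covariance of the estimator, used by [smooth_scan()] to account for the
#' correlation between scan points computed on the same cohort.
#'
#' @param fit a converged [fit_cox()] object.
#' @param data the [survival_data()] it was fit to.
#' @return an n x p matrix, rows in the order of `data`.
#' @export
cox_dfbeta <- function(fit, data) {
  stopifnot(inherits(fit, "cox_fit"), inherits(data, "survival_data"))
  if (!fit$converged) stop("cox_dfbeta: fit did not converge", call. = FALSE)
  prep <- cox_prep(data$time, data$event, data$X)
  L <- cox_score_residuals_prep(prep, fit$beta)
  D <- L %*% fit$cov
  # undo the time sort
  ord <- order(data$time)
  out <- matrix(NA_real_, nrow(D), ncol(D))
  out[ord, ] <- D
  colnames(out) <- colnames(data$X)
  out
}
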