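# Brute-force partial-likelihood grid maximizer, written independently of the
# package internals (direct risk-set arithmetic on a beta grid). Oracle for
# the Newton-Raphson fitter on single-covariate datasets.
grid_max_loglik <- function(time, event, x, ties = "breslow",
                            lo = -5, hi = 5, step = 1e-4) {
  bgrid <- seq(lo, hi, by = step)
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; x_s <- x[ord]
  n <- length(t_s)
  M <- exp(outer(x_s, bgrid))                 # n x G
  S <- M
  if (n > 1) for (i in (n - 1):1) S[i, ] <- S[i, ] + S[i + 1, ]
  first <- match(t_s, t_s)
  ev <- which(e_s == 1)
  ll <- colSums(outer(x_s[ev], bgrid))
  if (ties == "breslow") {
    ll <- ll - colSums(log(S[first[ev], , drop = FALSE]))
  } else {
    evt <- t_s[ev]
    for (ut in unique(evt)) {
      idx <- ev[evt == ut]
      d <- length(idx)
      ri <- first[idx[1]]
      D <- colSums(M[idx, , drop = FALSE])
      for (k in seq_len(d) - 1L) ll <- ll - log(S[ri, ] - (k / d) * D)
    }
  }
  bgrid[which.max(ll)]
}

# fixture suite of single-covariate survival datasets with <= 8 subjects
# (censoring, ties, binary and continuous covariates)
small_cox_fixtures <- function() {
  fx <- list(
    list(time = c(1, 2), event = c(1, 1), x = c(1, 0)),
    list(time = c(1, 1), event = c(1, 1), x = c(1, 0)),
    list(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1), x = c(1, 0, 1, 0)),
    list(time = c(2, 4, 4, 6, 7), event = c(1, 1, 0, 1, 0), x = c(1, 1, 0, 0, 1)),
    list(time = c(1, 1, 2, 3, 3, 5), event = c(1, 1, 1, 0, 1, 1),
         x = c(0, 1, 1, 0, 1, 0)),
    list(time = c(3, 1, 4, 1, 5, 9, 2, 6), event = c(1, 0, 1, 1, 0, 1, 1, 0),
         x = c(0.5, -1, 2, 0, 1.5, -0.5, 1, 0.2))
  )
  set.seed(420)
  for (i in 1:6) {
    n <- sample(4:8, 1)
    fx[[length(fx) + 1]] <- list(
      time = sample(1:6, n, replace = TRUE),
      event = pmax(rbinom(n, 1, 0.7), c(1, rep(0, n - 1))),
      x = round(rnorm(n), 2)
    )
  }
  # keep only fixtures with a non-constant covariate and >= 1 event
  Filter(function(f) sd(f$x) > 0 && sum(f$event) >= 1, fx)
}

# cohort reconstructed from the printed group sizes and counts of the study's
# baseline table (values that matter for the table builder; remaining columns
# filled with valid placeholders)
make_printed_cohort <- function() {
  n_surv <- 113; n_dead <- 86
  n <- n_surv + n_dead
  event <- rep(c(0, 1), c(n_surv, n_dead))
  fill_flag <- function(k_surv, k_dead) {
    c(rep(c(1, 0), c(k_surv, n_surv - k_surv)),
      rep(c(1, 0), c(k_dead, n_dead - k_dead)))
  }
  vasopressor <- fill_flag(39, 64)
  hemodialysis <- fill_flag(15, 30)
  mech_vent <- fill_flag(69, 68)
  male <- fill_flag(65, 46)
  known_dm <- fill_flag(26, 24)
  # among the 149 without known DM: 51 prediabetes, 16 diabetes, 82 normal
  hba1c <- numeric(n)
  hba1c[known_dm == 1] <- 7.5
  no_dm <- which(known_dm == 0)
  hba1c[no_dm[1:51]] <- 6.0                   # prediabetes [5.7, 6.5)
  hba1c[no_dm[52:67]] <- 7.0                  # unrecognized diabetes >= 6.5
  hba1c[no_dm[68:149]] <- 5.0                 # normal < 5.7
  data.frame(
    id = sprintf("P%04d", 1:n),
    age = rep(c(56, 61), c(n_surv, n_dead)) + rep_len(c(-1, 0, 1), n),
    male = male,
    apache2 = rep(c(18, 25), c(n_surv, n_dead)) + rep_len(c(-2, 0, 2), n),
    sofa = rep(c(5, 8), c(n_surv, n_dead)) + rep_len(0:2, n),
    bmi = rep(c(27.2, 24.7), c(n_surv, n_dead)) + rep_len(c(-3, 0, 3), n),
    hba1c = hba1c,
    known_dm = known_dm,
    time = rep_len(c(8, 16, 28, 40), n),
    event = event,
    mech_vent = mech_vent, hemodialysis = hemodialysis,
    vasopressor = vasopressor,
    lactate = rep_len(c(6, 9, 15, 30), n),
    crp = rep_len(c(30, 90, 150), n),
    glucose = rep_len(c(99, 122, 160), n),
    hemoglobin = rep_len(c(9, 10.8, 12.5), n),
    stringsAsFactors = FALSE
  )
}

# percentage embedded in a "count (pct)" Table-1 summary string
pct_of <- function(s) as.numeric(sub(".*\\(([-0-9.]+)\\).*", "\\1", s))

table1_row <- function(tb, var) tb$rows[tb$rows$variable == var, , drop = FALSE]

## validation-experiment configurations (study conditions; also stated in the
## methods vignette and reused by scripts/acceptance.R)
recovery_config <- function(n = 2000) {
  cohort_config(n_patients = n,
                hba1c_dist = list(meanlog = log(6.0), sdlog = 0.28,
                                  lo = 3.5, hi = 18),
                hba1c_effect = threshold_effect(9.3, log(1.74)),
                bmi_effect = null_effect())
}

null_config <- function(n = 199) {
  cohort_config(n_patients = n,
                hba1c_effect = null_effect(), bmi_effect = null_effect(),
                apache_loghr_per_point = 0,
                baseline_hazard_per_day = 0.0167)
}

shape_config <- function(n = 2000) {
  cohort_config(n_patients = n,
                hba1c_effect = null_effect(),
                bmi_effect = piecewise_effect(c(24, 30), c(-0.075, 0, -0.075)))
}

hba1c_scan_spec <- function() {
  scan_spec("hba1c", 4.5, 12, 0.25, direction = "risk-above",
            adjust_for = "apache2")
}

bmi_scan_spec <- function() {
  scan_spec("bmi", 20, 35, 0.5, direction = "risk-below",
            adjust_for = "apache2")
}

# hand-constructed scan-point tables (no influence information)
fake_scan_points <- function(cutoff, loghr, se, spec) {
  pts <- data.frame(cutoff = cutoff, loghr = loghr, se = se,
                    hr = exp(loghr), n_low = 50, n_high = 50,
                    events_low = 20, events_high = 20,
                    converged = TRUE, usable = TRUE)
  structure(pts, class = c("scan_points", "data.frame"), spec = spec)
}
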