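#' Configuration of the synthetic ICU cohort generator
#'
#' Defines the full parameterization of a simulated intensive-care cohort:
#' marginal covariate distributions, the BMI-HbA1c dependence (a Gaussian
#' copula calibrated to a target squared correlation), the true covariate
#' effects on the log hazard of in-hospital death, and an independent
#' exponential discharge (censoring) process. The defaults emulate a
#' ~200-patient mixed medical/surgical ICU cohort with ~43% in-hospital
#' mortality, a median follow-up around 16 days, weakly correlated BMI and
#' HbA1c (r^2 = 0.05), a step increase in mortality hazard at HbA1c >= 9.3%
#' (HR 1.74) and a shallow U-shaped BMI effect.
#'
#' @param n_patients cohort size (>= 2).
#' @param bmi_dist truncated-normal marginal for BMI: `list(mean, sd, lo, hi)`
#'   in kg/m^2.
#' @param hba1c_dist truncated-log-normal marginal for HbA1c:
#'   `list(meanlog, sdlog, lo, hi)` on the % (NGSP) scale.
#' @param bmi_hba1c_r2 target squared correlation between BMI and HbA1c, in
#'   `[0, 1)`.
#' @param hgb_dist truncated-normal marginal for hemoglobin (g/dL).
#' @param hba1c_hgb_r2 target squared correlation between HbA1c and
#'   hemoglobin, in `[0, 1)`.
#' @param apache_dist truncated-normal marginal for the APACHE II score
#'   (points, truncated to `[0, 71]`).
#' @param hba1c_effect,bmi_effect [effect_spec] objects giving the true
#'   log-hazard contribution of HbA1c and BMI.
#' @param apache_loghr_per_point log hazard ratio per APACHE II point.
#' @param baseline_hazard_per_day baseline death hazard (per day, > 0) at
#'   covariate contribution zero.
#' @param discharge_rate_per_day rate (per day, > 0) of the independent
#'   exponential discharge-alive process that censors follow-up.
#' @param max_followup_days administrative censoring horizon (days).
#' @return an object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 199,
                          bmi_dist = list(mean = 26.1, sd = 6.6, lo = 13, hi = 60),
                          hba1c_dist = list(meanlog = log(5.75), sdlog = 0.15,
                                            lo = 3.5, hi = 18),
                          bmi_hba1c_r2 = 0.05,
                          hgb_dist = list(mean = 10.8, sd = 2.3, lo = 4, hi = 18),
                          hba1c_hgb_r2 = 0.026,
                          apache_dist = list(mean = 20.7, sd = 8.6, lo = 0, hi = 71),
                          hba1c_effect = threshold_effect(9.3, log(1.74)),
                          bmi_effect = piecewise_effect(c(24, 30), c(-0.075, 0, -0.075)),
                          apache_loghr_per_point = 0.10,
                          baseline_hazard_per_day = 0.00196,
                          discharge_rate_per_day = 0.0220,
                          max_followup_days = 365) {
  cfg <- structure(list(
    n_patients = n_patients,
    bmi_dist = bmi_dist, hba1c_dist = hba1c_dist,
    bmi_hba1c_r2 = bmi_hba1c_r2,
    hgb_dist = hgb_dist, hba1c_hgb_r2 = hba1c_hgb_r2,
    apache_dist = apache_dist,
    hba1c_effect = hba1c_effect, bmi_effect = bmi_effect,
    apache_loghr_per_point = apache_loghr_per_point,
    baseline_hazard_per_day = baseline_hazard_per_day,
    discharge_rate_per_day = discharge_rate_per_day,
    max_followup_days = max_followup_days
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid cohort configuration: field '%s' %s", field, why),
         call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$n_patients) || cfg$n_patients < 2 ||
      cfg$n_patients != round(cfg$n_patients))
    bad("n_patients", "must be an integer >= 2")
  for (f in c("bmi_dist", "hgb_dist", "apache_dist")) {
    d <- cfg[[f]]
    if (!num1(d$mean) || !num1(d$sd) || d$sd <= 0) bad(f, "needs mean and sd > 0")
    if (!num1(d$lo) || !num1(d$hi) || d$lo >= d$hi)
      bad(f, "truncation bounds must satisfy lo < hi")
  }
  d <- cfg$hba1c_dist
  if (!num1(d$meanlog) || !num1(d$sdlog) || d$sdlog <= 0)
    bad("hba1c_dist", "needs meanlog and sdlog > 0")
  if (!num1(d$lo) || !num1(d$hi) || d$lo <= 0 || d$lo >= d$hi)
    bad("hba1c_dist", "truncation bounds must satisfy 0 < lo < hi")
  for (f in c("bmi_hba1c_r2", "hba1c_hgb_r2"))
    if (!num1(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] >= 1)
      bad(f, "must lie in [0, 1)")
  for (f in c("hba1c_effect", "bmi_effect"))
    if (!inherits(cfg[[f]], "effect_spec")) bad(f, "must be an effect_spec")
  if (!num1(cfg$apache_loghr_per_point)) bad("apache_loghr_per_point", "must be finite")
  for (f in c("baseline_hazard_per_day", "discharge_rate_per_day"))
    if (!num1(cfg[[f]]) || cfg[[f]] <= 0) bad(f, "must be > 0")
  if (!num1(cfg$max_followup_days) || cfg$max_followup_days <= 0)
    bad("max_followup_days", "must be > 0")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic ICU cohort configuration\n")
  cat(sprintf("  n_patients: %d\n", x$n_patients))
  cat(sprintf("  BMI ~ truncN(%.1f, %.1f) on [%g, %g]; HbA1c ~ truncLN(%.3f, %.3f) on [%g, %g]\n",
              x$bmi_dist$mean, x$bmi_dist$sd, x$bmi_dist$lo, x$bmi_dist$hi,
              x$hba1c_dist$meanlog, x$hba1c_dist$sdlog, x$hba1c_dist$lo, x$hba1c_dist$hi))
  cat(sprintf("  BMI-HbA1c r^2: %.3f; HbA1c-Hgb r^2: %.3f\n",
              x$bmi_hba1c_r2, x$hba1c_hgb_r2))
  cat(sprintf("  APACHE II ~ truncN(%.1f, %.1f); log-HR/point: %.3f\n",
              x$apache_dist$mean, x$apache_dist$sd, x$apache_loghr_per_point))
  cat(sprintf("  baseline hazard %.5f/day, discharge rate %.4f/day, horizon %g days\n",
              x$baseline_hazard_per_day, x$discharge_rate_per_day, x$max_followup_days))
  invisible(x)
}

# quantile of a truncated normal via probability-integral transform
qtnorm <- function(u, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

qtlnorm <- function(u, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(plo + u * (phi - plo), meanlog, sdlog)
}

#' Generate a synthetic ICU cohort
#'
#' Draws one admission per row. BMI, HbA1c and hemoglobin are coupled through
#' a Gaussian copula whose pairwise correlations are the square roots of the
#' configured r^2 targets; marginals are the configured truncated
#' normal/log-normal distributions. The death time is exponential with
#' log-hazard `log(baseline) + hba1c_effect(hba1c) + bmi_effect(bmi) +
#' apache_loghr_per_point * apache2`; an independent exponential discharge
#' time censors it, and follow-up is capped at `max_followup_days`. Four
#' seed-derived substreams (covariates, death, discharge, treatment flags)
#' keep each stage reproducible on its own.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; identical `(config, seed)` gives a bit-identical
#'   cohort.
#' @return a `data.frame` with one row per patient and columns `id`, `age`,
#'   `male`, `apache2`, `sofa`, `bmi`, `hba1c`, `known_dm`, `time`, `event`,
#'   `mech_vent`, `hemodialysis`, `vasopressor`, `lactate`, `crp`, `glucose`,
#'   `hemoglobin`. `time` is in days (> 0); `event` is 1 for in-hospital
#'   death, 0 for discharge alive / administrative censoring.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  seed <- as.integer(seed)
  n <- config$n_patients

  ## stream 1: covariates ----------------------------------------------------
  set.seed(seed)
  r_bh <- sqrt(config$bmi_hba1c_r2)
  r_hg <- sqrt(config$hba1c_hgb_r2)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- r_bh   # bmi - hba1c
  R[2, 3] <- R[3, 2] <- r_hg   # hba1c - hemoglobin
  L <- chol(R)
  Z <- matrix(stats::rnorm(3L * n), nrow = n) %*% L
  U <- stats::pnorm(Z)
  bmi <- qtnorm(U[, 1], config$bmi_dist$mean, config$bmi_dist$sd,
                config$bmi_dist$lo, config$bmi_dist$hi)
  hba1c <- qtlnorm(U[, 2], config$hba1c_dist$meanlog, config$hba1c_dist$sdlog,
                   config$hba1c_dist$lo, config$hba1c_dist$hi)
  hemoglobin <- qtnorm(U[, 3], config$hgb_dist$mean, config$hgb_dist$sd,
                       config$hgb_dist$lo, config$hgb_dist$hi)
  apache2 <- qtnorm(stats::runif(n), config$apache_dist$mean, config$apache_dist$sd,
                    config$apache_dist$lo, config$apache_dist$hi)
  age <- round(qtnorm(stats::runif(n), 58, 17.3, 18, 100))
  male <- as.integer(stats::runif(n) < 0.558)
  sofa <- pmin(24, pmax(0, round(0.35 * apache2 + stats::rnorm(n, 0, 2.2))))
  known_dm <- as.integer(stats::runif(n) < stats::plogis(-3.6 + 0.40 * hba1c))
  glucose <- stats::rlnorm(n, log(110) + 0.08 * pmax(hba1c - 5.7, 0), 0.35)
  lactate <- stats::rlnorm(n, log(11), 0.62)
  crp <- stats::rlnorm(n, log(90), 0.85)

  ## stream 2: death times ---------------------------------------------------
  set.seed(seed + 1L)
  loghaz <- log(config$baseline_hazard_per_day) +
    effect_loghr(config$hba1c_effect, hba1c) +
    effect_loghr(config$bmi_effect, bmi) +
    config$apache_loghr_per_point * apache2
  t_death <- stats::rexp(n) / exp(loghaz)

  ## stream 3: discharge (censoring) times -----------------------------------
  set.seed(seed + 2L)
  t_disc <- stats::rexp(n) / config$discharge_rate_per_day

  ## stream 4: treatment flags -----------------------------------------------
  set.seed(seed + 3L)
  za <- (apache2 - config$apache_dist$mean) / config$apache_dist$sd
  vasopressor <- as.integer(stats::runif(n) < stats::plogis(0.08 + 1.0 * za))
  mech_vent <- as.integer(stats::runif(n) < stats::plogis(0.90 + 0.7 * za))
  hemodialysis <- as.integer(stats::runif(n) < stats::plogis(-1.45 + 0.8 * za))

  time <- pmin(t_death, t_disc, config$max_followup_days)
  event <- as.integer(t_death <= t_disc & t_death <= config$max_followup_days)

  data.frame(
    id = sprintf("P%04d", seq_len(n)),
    age = age, male = male,
    apache2 = round(apache2), sofa = sofa,
    bmi = round(bmi, 1), hba1c = round(hba1c, 1),
    known_dm = known_dm,
    time = pmax(round(time, 3), 0.001), event = event,
    mech_vent = mech_vent, hemodialysis = hemodialysis,
    vasopressor = vasopressor,
    lactate = round(lactate, 1), crp = round(crp, 1),
    glucose = round(glucose, 0), hemoglobin = round(hemoglobin, 1),
    stringsAsFactors = FALSE
  )
}

cohort_columns <- c("id", "age", "male", "apache2", "sofa", "bmi", "hba1c",
                    "known_dm", "time", "event", "mech_vent", "hemodialysis",
                    "vasopressor", "lactate", "crp", "glucose", "hemoglobin")

#' Read and write cohort tables
#'
#' The cohort interchange format is a plain UTF-8 CSV with a header row, "."
#' decimal separator, and exactly the columns documented in
#' [generate_cohort()]. `read_cohort()` validates the schema and rejects
#' missing values.
#'
#' @param cohort a cohort `data.frame`.
#' @param path file path.
#' @return `read_cohort()` returns the validated `data.frame`;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort[, cohort_columns], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(cohort)
  cohort
}

validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num_cols <- setdiff(cohort_columns, "id")
  for (cl in num_cols) {
    if (anyNA(cohort[[cl]]))
      stop("cohort schema error: missing values in column ", cl, call. = FALSE)
  }
  if (any(cohort$time <= 0))
    stop("cohort schema error: column time must be > 0", call. = FALSE)
  if (!all(cohort$event %in% c(0, 1)))
    stop("cohort schema error: column event must be 0/1", call. = FALSE)
  if (any(cohort$bmi <= 0) || any(cohort$hba1c <= 0))
    stop("cohort schema error: bmi and hba1c must be > 0", call. = FALSE)
  invisible(cohort)
}

#' Save or load a generator configuration as JSON
#'
#' @param config a [cohort_config()].
#' @param path file path of the JSON document.
#' @return `read_cohort_config()` returns a `cohort_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
write_cohort_config <- function(config, path) {
  validate_cohort_config(config)
  x <- unclass(config)
  x$hba1c_effect <- effect_to_list(config$hba1c_effect)
  x$bmi_effect <- effect_to_list(config$bmi_effect)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_config(
    n_patients = x$n_patients,
    bmi_dist = as.list(x$bmi_dist), hba1c_dist = as.list(x$hba1c_dist),
    bmi_hba1c_r2 = x$bmi_hba1c_r2,
    hgb_dist = as.list(x$hgb_dist), hba1c_hgb_r2 = x$hba1c_hgb_r2,
    apache_dist = as.list(x$apache_dist),
    hba1c_effect = effect_from_list(as.list(x$hba1c_effect)),
    bmi_effect = effect_from_list(as.list(x$bmi_effect)),
    apache_loghr_per_point = x$apache_loghr_per_point,
    baseline_hazard_per_day = x$baseline_hazard_per_day,
    discharge_rate_per_day = x$discharge_rate_per_day,
    max_followup_days = x$max_followup_days
  )
}
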