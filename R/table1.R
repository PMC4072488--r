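#' ADA glucose-tolerance classification from HbA1c
#'
#' Categorizes glycemic history by HbA1c (%, NGSP): normal `< 5.7`,
#' prediabetes `[5.7, 6.5)`, diabetes `>= 6.5`. A known history of diabetes
#' overrides the HbA1c value.
#'
#' @param hba1c HbA1c in % (> 0).
#' @param known_dm logical/0-1 flag of known diabetes history.
#' @return factor with levels `normal`, `prediabetes`, `diabetes`.
#' @examples
#' classify_glucose(c(5.6, 6.4, 6.5, 5.0), known_dm = c(0, 0, 0, 1))
#' @export
classify_glucose <- function(hba1c, known_dm = 0) {
  if (any(hba1c <= 0)) stop("classify_glucose: hba1c must be > 0", call. = FALSE)
  known_dm <- rep_len(as.integer(known_dm), length(hba1c))
  lab <- ifelse(known_dm == 1L, "diabetes",
                ifelse(hba1c < 5.7, "normal",
                       ifelse(hba1c < 6.5, "prediabetes", "diabetes")))
  factor(lab, levels = c("normal", "prediabetes", "diabetes"))
}

#' WHO body-mass-index categories
#'
#' Lower-inclusive bins at 18.5, 25, 30 and 40 kg/m^2: underweight,
#' normal weight, overweight, class I-II obesity, extreme obesity. The WHO
#' labels quote the bins as 18.5-24.9 etc.; boundary values such as 24.95 or
#' exactly 40 are assigned with half-open lower-inclusive intervals, the
#' standard convention.
#'
#' @param bmi BMI in kg/m^2 (> 0).
#' @return factor with levels `underweight`, `normal`, `overweight`,
#'   `obesity I-II`, `extreme obesity`.
#' @export
classify_bmi <- function(bmi) {
  if (any(bmi <= 0)) stop("classify_bmi: bmi must be > 0", call. = FALSE)
  lev <- c("underweight", "normal", "overweight", "obesity I-II",
           "extreme obesity")
  factor(lev[findInterval(bmi, c(18.5, 25, 30, 40)) + 1L], levels = lev)
}

#' Two-group comparison in the Table-1 style
#'
#' Compares a variable between two groups with the test matching its type:
#' Student t with pooled variance for normally-summarized continuous
#' variables, Mann-Whitney U (Wilcoxon rank-sum) for skewed ones, and
#' Pearson chi-square without continuity correction for categoricals.
#'
#' @param values the variable (numeric, or 0/1 / factor for categorical).
#' @param group two-level grouping vector.
#' @param type `"continuous-normal"`, `"continuous-skewed"` or
#'   `"categorical"`.
#' @return a list with `summary` (one formatted string per group),
#'   `statistic`, `p` and `test`.
#' @export
compare_groups <- function(values, group,
                           type = c("continuous-normal", "continuous-skewed",
                                    "categorical")) {
  type <- match.arg(type)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2)
    stop("compare_groups: exactly two non-empty groups are required",
         call. = FALSE)
  g <- split(values, group)
  if (type == "continuous-normal") {
    if (stats::sd(g[[1]]) == 0 && stats::sd(g[[2]]) == 0)
      stop("compare_groups: zero variance in both groups", call. = FALSE)
    tt <- stats::t.test(g[[1]], g[[2]], var.equal = TRUE)
    list(summary = vapply(g, function(v)
           sprintf("%.1f ± %.1f", mean(v), stats::sd(v)), character(1)),
         statistic = unname(tt$statistic), p = tt$p.value,
         test = "Student t (pooled)")
  } else if (type == "continuous-skewed") {
    wt <- suppressWarnings(stats::wilcox.test(g[[1]], g[[2]], exact = FALSE,
                                              correct = TRUE))
    list(summary = vapply(g, function(v) {
           q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
           sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
         }, character(1)),
         statistic = unname(wt$statistic), p = wt$p.value,
         test = "Mann-Whitney U")
  } else {
    tab <- table(values, group)
    if (nrow(tab) < 2) {
      # degenerate category (e.g. a flag that never occurs): no test
      return(list(summary = vapply(seq_len(ncol(tab)), function(i)
                    sprintf("%d (%.1f)", 0L, 0), character(1)),
                  statistic = NA_real_, p = NA_real_,
                  test = "chi-square (skipped: degenerate category)"))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    sum_fun <- function(i) {
      n1 <- if (is.numeric(values)) sum(g[[i]] == 1) else
        sum(g[[i]] == levels(as.factor(values))[2])
      sprintf("%d (%.1f)", n1, round(100 * n1 / length(g[[i]]), 1))
    }
    list(summary = vapply(seq_along(g), sum_fun, character(1)),
         statistic = unname(ct$statistic), p = ct$p.value,
         test = "Pearson chi-square")
  }
}

#' Squared correlation with a test of zero correlation
#'
#' @param x,y numeric vectors (n >= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return a list with `r2` (squared correlation coefficient) and `p`
#'   (two-sided test of zero correlation).
#' @export
correlation_r2 <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) < 3 || length(y) != length(x))
    stop("correlation_r2: need matched vectors with n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation_r2: constant input", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(r2 = unname(ct$estimate)^2, p = ct$p.value)
}

# variable map: which test/summary style each Table-1 variable gets
table1_variables <- function() {
  rbind(
    data.frame(variable = c("age", "apache2", "bmi"),
               type = "continuous-normal"),
    data.frame(variable = c("sofa", "hba1c", "glucose", "lactate", "crp"),
               type = "continuous-skewed"),
    data.frame(variable = c("male", "known_dm", "mech_vent", "hemodialysis",
                            "vasopressor"),
               type = "categorical")
  )
}

#' Build the descriptive cohort table (survivors vs nonsurvivors)
#'
#' Reproduces the layout of the classic ICU baseline table: per-variable
#' summaries for survivors and nonsurvivors with the appropriate two-group
#' test (see [compare_groups()]), a three-level glucose-tolerance comparison,
#' and overall cohort statistics — group sizes, in-hospital mortality, the
#' share of patients without a known diabetes history, and the
#' prediabetes/unrecognized-diabetes breakdown among them. Percentages are
#' computed within group and rounded to one decimal.
#'
#' @param cohort a cohort `data.frame` (schema of [generate_cohort()]).
#' @return an object of class `table1`: list with `n` (named group sizes),
#'   `rows` (per-variable `data.frame`), and `overall`.
#' @export
build_table1 <- function(cohort) {
  validate_cohort(cohort)
  surv <- cohort$event == 0
  vars <- table1_variables()
  rows <- do.call(rbind, lapply(seq_len(nrow(vars)), function(i) {
    v <- vars$variable[i]
    cmp <- compare_groups(cohort[[v]],
                          factor(ifelse(surv, "survivor", "nonsurvivor"),
                                 levels = c("survivor", "nonsurvivor")),
                          vars$type[i])
    data.frame(variable = v, type = vars$type[i],
               survivors = cmp$summary[1], nonsurvivors = cmp$summary[2],
               statistic = cmp$statistic, p = cmp$p, test = cmp$test,
               stringsAsFactors = FALSE)
  }))
  ## glucose tolerance (3 categories, chi-square across survival)
  gt <- classify_glucose(cohort$hba1c, cohort$known_dm)
  gt_tab <- table(gt, surv)
  gt_test <- suppressWarnings(stats::chisq.test(gt_tab, correct = FALSE))
  gt_row <- data.frame(
    variable = "glucose_tolerance", type = "categorical",
    survivors = paste(sprintf("%s %d (%.1f)", levels(gt),
                              gt_tab[, "TRUE"],
                              round(100 * gt_tab[, "TRUE"] / sum(surv), 1)),
                      collapse = "; "),
    nonsurvivors = paste(sprintf("%s %d (%.1f)", levels(gt),
                                 gt_tab[, "FALSE"],
                                 round(100 * gt_tab[, "FALSE"] / sum(!surv), 1)),
                         collapse = "; "),
    statistic = unname(gt_test$statistic), p = gt_test$p.value,
    test = "Pearson chi-square", stringsAsFactors = FALSE)
  rows <- rbind(rows, gt_row)
  rownames(rows) <- NULL

  n <- nrow(cohort)
  deaths <- sum(cohort$event)
  no_dm <- cohort$known_dm == 0
  gt_no_dm <- classify_glucose(cohort$hba1c[no_dm], 0)
  overall <- list(
    n = n, deaths = deaths,
    mortality_pct = round(100 * deaths / n, 1),
    median_followup = unname(stats::quantile(cohort$time, 0.5)),
    no_known_dm_n = sum(no_dm),
    no_known_dm_pct = round(100 * sum(no_dm) / n, 1),
    prediabetes_no_dm_n = sum(gt_no_dm == "prediabetes"),
    prediabetes_no_dm_pct = round(100 * mean(gt_no_dm == "prediabetes"), 1),
    unrecognized_dm_n = sum(gt_no_dm == "diabetes"),
    unrecognized_dm_pct = round(100 * mean(gt_no_dm == "diabetes"), 1)
  )
  structure(list(
    n = c(survivors = sum(surv), nonsurvivors = sum(!surv)),
    rows = rows, overall = overall
  ), class = "table1")
}

#' @export
print.table1 <- function(x, ...) {
  cat(sprintf("Cohort characteristics by survival: %d survivors, %d nonsurvivors\n",
              x$n["survivors"], x$n["nonsurvivors"]))
  cat(sprintf("Overall in-hospital mortality: %d/%d (%.1f%%)\n",
              x$overall$deaths, x$overall$n, x$overall$mortality_pct))
  cat(sprintf("No known DM history: %d (%.1f%%); among them prediabetes %d (%.1f%%), unrecognized DM %d (%.1f%%)\n",
              x$overall$no_known_dm_n, x$overall$no_known_dm_pct,
              x$overall$prediabetes_no_dm_n, x$overall$prediabetes_no_dm_pct,
              x$overall$unrecognized_dm_n, x$overall$unrecognized_dm_pct))
  tab <- x$rows
  tab$p <- ifelse(tab$p < 0.001, "<0.001", sprintf("%.3f", tab$p))
  print(tab[, c("variable", "survivors", "nonsurvivors", "p")],
        row.names = FALSE, right = FALSE)
  invisible(x)
}

#' @export
as.data.frame.table1 <- function(x, ...) x$rows
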