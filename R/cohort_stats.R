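# Cohort-level statistics: Welch and paired t-tests, Fisher's exact test,
# the two-group sample-size calculation, and group summary tables.

#' Group summary (n, mean, SD)
#'
#' @param n Group size (>= 2).
#' @param mean Group mean.
#' @param sd Group standard deviation (>= 0).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  check_scalar(n, "n", lower = 2, integer = TRUE)
  check_scalar(mean, "mean")
  check_scalar(sd, "sd", lower = 0)
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

as_group_summary <- function(x, name) {
  if (inherits(x, "group_summary")) return(x)
  if (is.numeric(x)) {
    if (length(x) < 2L)
      insufficient_data_error(sprintf("group '%s' needs at least 2 observations", name))
    return(group_summary(length(x), mean(x), stats::sd(x)))
  }
  input_error(sprintf("'%s' must be a numeric sample or a group_summary", name))
}

test_result <- function(method, statistic, df, p.value, ...) {
  structure(list(method = method, statistic = statistic, df = df,
                 p.value = p.value, ...),
            class = "mpri_test")
}

#' @export
print.mpri_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test, accepting either raw samples or `(n, mean, sd)`
#' summaries: `t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param a,b Numeric samples or [group_summary()] objects.
#' @return An `mpri_test` with `statistic`, `df` (fractional), `p.value`.
#' @examples
#' welch_t(group_summary(10, -48, 11), group_summary(10, -35, 12))
#' @export
welch_t <- function(a, b) {
  a <- as_group_summary(a, "a")
  b <- as_group_summary(b, "b")
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  se2 <- va + vb
  diff <- a$mean - b$mean
  if (se2 == 0) {
    if (diff == 0)
      zero_variance_error("both groups have zero variance and equal means; t is undefined")
    return(test_result("Welch two-sample t-test", sign(diff) * Inf, Inf, 0))
  }
  t <- diff / sqrt(se2)
  df <- se2^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  test_result("Welch two-sample t-test", t, df,
              2 * stats::pt(-abs(t), df))
}

#' Paired t-test on per-subject differences
#'
#' One-sample t-test of the differences against zero (df = n - 1, two-sided).
#'
#' @param differences Numeric vector of per-subject differences (n >= 2, with
#'   non-zero spread).
#' @return An `mpri_test`.
#' @export
paired_t <- function(differences) {
  if (!is.numeric(differences) || length(differences) < 2L)
    insufficient_data_error("paired test needs at least 2 differences")
  if (any(!is.finite(differences)))
    input_error("differences must be finite")
  if (stats::sd(differences) == 0)
    zero_variance_error("differences have zero variance; paired t is undefined")
  ht <- stats::t.test(differences)
  test_result("Paired t-test", unname(ht$statistic), unname(ht$parameter),
              ht$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities, over all tables with the observed margins, of
#' tables no more probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return An `mpri_test`; `statistic` is the conditional MLE odds ratio,
#'   `df` is `NA`.
#' @examples
#' fisher_exact_2x2(matrix(c(7, 5, 3, 5), 2))  # p ~ 0.65
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == c(2L, 2L)))
    input_error("'table' must be a 2x2 matrix")
  if (any(!is.finite(table)) || any(table < 0) || any(table != round(table)))
    input_error("counts must be non-negative integers")
  if (sum(table) < 1)
    input_error("the table must contain at least one observation")
  ht <- stats::fisher.test(table)
  test_result("Fisher's exact test", unname(ht$estimate), NA_real_,
              ht$p.value)
}

#' Two-group sample size for a relative difference in means
#'
#' Computes the total number of subjects needed to detect a relative
#' difference `rel_diff` from a reference mean with common SD `sd`, two-sided
#' level `alpha` and the given power, with equal allocation. The default
#' normal-approximation formula is
#' `n_per_group = ceiling(2 * sd^2 * (z_{1-alpha/2} + z_{power})^2 / delta^2)`
#' with `delta = rel_diff * mean`. `method = "exact"` instead solves the
#' noncentral-t power equation ([stats::power.t.test()]), which returns a
#' slightly larger n.
#'
#' @param mean Reference group mean (> 0).
#' @param sd Common standard deviation (> 0).
#' @param rel_diff Relative difference to detect, in (0, 1].
#' @param alpha Two-sided type-I error rate.
#' @param power Target power.
#' @param method `"normal"` (default) or `"exact"`.
#' @return List with `n_per_group`, `n_total`, `delta`, `method`.
#' @examples
#' sample_size_two_group(1.78, 0.60, 0.25)$n_total  # 58
#' @export
sample_size_two_group <- function(mean, sd, rel_diff, alpha = 0.05,
                                  power = 0.80,
                                  method = c("normal", "exact")) {
  check_scalar(mean, "mean", lower = 0, strict_lower = TRUE)
  check_scalar(sd, "sd", lower = 0, strict_lower = TRUE)
  check_scalar(rel_diff, "rel_diff", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(power, "power", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  method <- match.arg(method)
  delta <- rel_diff * mean
  if (delta == 0) domain_error("the detectable difference is zero")
  n_per <- if (method == "normal") {
    ceiling(2 * sd^2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 /
              delta^2)
  } else {
    ceiling(stats::power.t.test(delta = delta, sd = sd, sig.level = alpha,
                                power = power)$n)
  }
  n_per <- as.integer(n_per)
  list(n_per_group = n_per, n_total = 2L * n_per, delta = delta,
       method = method)
}

# Paired p-value that renders zero-variance (not-applicable) cells as NA.
paired_p_or_na <- function(differences) {
  tryCatch(paired_t(differences)$p.value,
           mpri_zero_variance_error = function(e) NA_real_,
           mpri_insufficient_data_error = function(e) NA_real_)
}

welch_p_or_na <- function(a, b) {
  tryCatch(welch_t(a, b)$p.value,
           mpri_zero_variance_error = function(e) NA_real_)
}

#' Cohort summary tables and tests
#'
#' Produces, per group, mean (SD) of the rest/stress/recovery up-slopes,
#' MPRi-rest, MPRi-recov and per-subject percent reduction, with paired
#' t-tests within group (recovery vs rest, recovery vs stress, MPRi-recov vs
#' MPRi-rest) and Welch t-tests between groups for every measure. Zero
#' variance within a group renders the affected p-value as `NA`.
#'
#' @param results data.frame with one row per subject and columns `id`,
#'   `group`, `rest`, `stress`, `recovery`, `mpri_rest`, `mpri_recov`,
#'   `pct_reduction` (as produced by [analyze_cohort()] and
#'   `as.data.frame.subject_perfusion`). A `delayed` column, if present, is
#'   tallied.
#' @return List of class `cohort_summary`: `group_table` (one row per group),
#'   `between` (Welch p per measure, `NULL` with a single group), `n_groups`.
#' @export
summarize_cohort <- function(results) {
  required <- c("id", "group", "rest", "stress", "recovery",
                "mpri_rest", "mpri_recov", "pct_reduction")
  missing_cols <- setdiff(required, names(results))
  if (length(missing_cols) > 0L)
    input_error(sprintf("results are missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(results$id))
    input_error("duplicated subject ids in the cohort results")
  groups <- unique(results$group)
  measures <- c("rest", "stress", "recovery", "mpri_rest", "mpri_recov",
                "pct_reduction")
  rows <- lapply(groups, function(g) {
    d <- results[results$group == g, , drop = FALSE]
    if (nrow(d) < 2L)
      insufficient_data_error(sprintf(
        "group '%s' has fewer than 2 subjects", g))
    row <- data.frame(group = g, n = nrow(d), stringsAsFactors = FALSE)
    for (m in measures) {
      row[[paste0(m, "_mean")]] <- mean(d[[m]])
      row[[paste0(m, "_sd")]] <- stats::sd(d[[m]])
    }
    row$p_recovery_vs_rest <- paired_p_or_na(d$recovery - d$rest)
    row$p_recovery_vs_stress <- paired_p_or_na(d$recovery - d$stress)
    row$p_mpri_recov_vs_rest <- paired_p_or_na(d$mpri_recov - d$mpri_rest)
    row$n_delayed <- if ("delayed" %in% names(d)) sum(d$delayed) else NA_integer_
    row
  })
  group_table <- do.call(rbind, rows)
  between <- NULL
  if (length(groups) == 2L) {
    d1 <- results[results$group == groups[1], , drop = FALSE]
    d2 <- results[results$group == groups[2], , drop = FALSE]
    between <- data.frame(
      measure = measures,
      p_between = vapply(measures, function(m) welch_p_or_na(d1[[m]], d2[[m]]),
                         numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  structure(list(group_table = group_table, between = between,
                 n_groups = length(groups)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat("Cohort perfusion summary\n")
  gt <- x$group_table
  fmt <- function(m, s) sprintf(paste0("%.", digits - 1, "f (%.", digits - 1, "f)"), m, s)
  disp <- data.frame(
    group = gt$group, n = gt$n,
    rest = fmt(gt$rest_mean, gt$rest_sd),
    stress = fmt(gt$stress_mean, gt$stress_sd),
    recovery = fmt(gt$recovery_mean, gt$recovery_sd),
    mpri_rest = fmt(gt$mpri_rest_mean, gt$mpri_rest_sd),
    mpri_recov = fmt(gt$mpri_recov_mean, gt$mpri_recov_sd),
    pct_reduction = fmt(gt$pct_reduction_mean, gt$pct_reduction_sd),
    p_mpri = ifelse(is.na(gt$p_mpri_recov_vs_rest), "n/a",
                    sprintf("%.3f", gt$p_mpri_recov_vs_rest)),
    stringsAsFactors = FALSE
  )
  print(disp, row.names = FALSE)
  if (!is.null(x$between)) {
    cat("\nBetween-group Welch tests\n")
    bt <- x$between
    bt$p_between <- ifelse(is.na(bt$p_between), "n/a",
                           sprintf("%.3f", bt$p_between))
    print(bt, row.names = FALSE)
  }
  invisible(x)
}
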