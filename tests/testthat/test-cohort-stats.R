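test_that("Welch test matches its closed form on summary input", {
  # identical summaries: t = 0, p = 1
  s <- group_summary(10, 5, 2)
  r0 <- welch_t(s, s)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)

  # heart-rate-change style row: summaries (-48, 11, 10) vs (-35, 12, 10).
  # Rounded summaries give p ~ 0.021; the raw-data value printed alongside
  # such tables (0.03) is not reproducible from summaries, so only the
  # closed-form value is asserted.
  r <- welch_t(group_summary(10, -48, 11), group_summary(10, -35, 12))
  expect_equal(r$statistic, -2.525343, tolerance = 1e-6)
  expect_equal(r$df, 17.86542, tolerance = 1e-6)
  expect_equal(r$p.value, 0.02124126, tolerance = 1e-6)
})

test_that("Welch test on samples equals t.test and the summary mode", {
  set.seed(31)
  for (i in 1:20) {
    a <- stats::rnorm(sample(5:30, 1), mean = stats::runif(1, -2, 2),
                      sd = stats::runif(1, 0.5, 3))
    b <- stats::rnorm(sample(5:30, 1), mean = stats::runif(1, -2, 2),
                      sd = stats::runif(1, 0.5, 3))
    mine <- welch_t(a, b)
    ref <- stats::t.test(a, b, var.equal = FALSE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$df, unname(ref$parameter))
    expect_equal(mine$p.value, ref$p.value)
    via_summary <- welch_t(group_summary(length(a), mean(a), stats::sd(a)),
                           group_summary(length(b), mean(b), stats::sd(b)))
    expect_equal(via_summary$p.value, mine$p.value)
    # antisymmetry
    flipped <- welch_t(b, a)
    expect_equal(flipped$statistic, -mine$statistic)
    expect_equal(flipped$p.value, mine$p.value)
  }
  expect_error(welch_t(group_summary(5, 1, 0), group_summary(5, 1, 0)),
               class = "mpri_zero_variance_error")
})

test_that("paired t-test matches hand computation and the textbook paired test", {
  r <- paired_t(c(1, 2, 3))
  expect_equal(r$statistic, 2 * sqrt(3))
  expect_equal(r$df, 2)
  expect_equal(r$p.value, 0.0741799, tolerance = 1e-6)

  set.seed(17)
  x <- stats::rnorm(12); y <- stats::rnorm(12)
  ref <- stats::t.test(x, y, paired = TRUE)
  mine <- paired_t(x - y)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p.value, ref$p.value)

  expect_error(paired_t(rep(2, 5)), class = "mpri_zero_variance_error")
  expect_error(paired_t(3), class = "mpri_insufficient_data_error")
})

test_that("Fisher's exact test reproduces the 7/10 vs 5/10 table and edge cases", {
  tab <- matrix(c(7, 5, 3, 5), 2)
  r <- fisher_exact_2x2(tab)
  expect_equal(r$p.value, 120076 / 184756, tolerance = 1e-9)
  expect_equal(round(r$p.value, 2), 0.65)

  # zero margin: only one admissible table
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 4, 6), 2))$p.value, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)),
               class = "mpri_input_error")
  expect_error(fisher_exact_2x2(matrix(0L, 2, 2)), class = "mpri_input_error")
})

test_that("hypergeometric probabilities over all admissible tables sum to one", {
  probs <- stats::dhyper(2:10, 10, 10, 12)
  expect_equal(sum(probs), 1)
  expect_equal(sum(probs), 184756 / 184756)
})

test_that("Fisher p agrees with exhaustive enumeration on random tables", {
  set.seed(23)
  for (i in 1:60) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab)$p.value, enumerate_fisher_p(tab),
                 tolerance = 1e-12)
  }
})

test_that("the normal-approximation sample size reproduces the two-group worked example", {
  r <- sample_size_two_group(mean = 1.78, sd = 0.60, rel_diff = 0.25,
                             alpha = 0.05, power = 0.80)
  expect_equal(r$n_per_group, 29)
  expect_equal(r$n_total, 58)
  exact <- sample_size_two_group(1.78, 0.60, 0.25, method = "exact")
  expect_gte(exact$n_total, r$n_total)
  expect_equal(exact$n_total, 60)
  expect_error(sample_size_two_group(1.78, 0.60, 0),
               class = "mpri_parameter_error")
})

test_that("sample size scales with variance and is monotone in its inputs", {
  base <- sample_size_two_group(1.78, 0.60, 0.25)
  quad <- sample_size_two_group(1.78, 1.20, 0.25)
  expect_gte(quad$n_per_group / base$n_per_group, 3.8)
  expect_lte(quad$n_per_group / base$n_per_group, 4.1)

  expect_gte(sample_size_two_group(1.78, 0.8, 0.25)$n_total, base$n_total)
  expect_gte(sample_size_two_group(1.78, 0.6, 0.25, power = 0.9)$n_total,
             base$n_total)
  expect_lte(sample_size_two_group(1.78, 0.6, 0.4)$n_total, base$n_total)
  expect_lte(sample_size_two_group(1.78, 0.6, 0.25, alpha = 0.1)$n_total,
             base$n_total)
})

test_that("cohort summary carries every required cell type", {
  set.seed(41)
  res <- constant_cohort_results()
  res$rest <- res$rest + stats::rnorm(nrow(res), sd = 0.3)
  res$stress <- res$stress + stats::rnorm(nrow(res), sd = 0.5)
  res$recovery <- res$recovery + stats::rnorm(nrow(res), sd = 0.4)
  res$mpri_rest <- res$stress / res$rest
  res$mpri_recov <- res$stress / res$recovery
  res$pct_reduction <- 100 * (res$mpri_rest - res$mpri_recov) / res$mpri_rest
  s <- summarize_cohort(res)
  gt <- s$group_table
  expect_setequal(
    names(gt),
    c("group", "n",
      paste0(rep(c("rest", "stress", "recovery", "mpri_rest", "mpri_recov",
                   "pct_reduction"), each = 2), c("_mean", "_sd")),
      "p_recovery_vs_rest", "p_recovery_vs_stress", "p_mpri_recov_vs_rest",
      "n_delayed"))
  expect_equal(gt$n, c(5, 5))
  expect_true(all(gt$p_recovery_vs_rest >= 0 & gt$p_recovery_vs_rest <= 1))
  expect_equal(nrow(s$between), 6)
  expect_true(all(s$between$p_between >= 0 & s$between$p_between <= 1,
                  na.rm = TRUE))
})

test_that("degenerate cohorts render zero-variance tests as not applicable", {
  res <- constant_cohort_results()
  s <- summarize_cohort(res)
  expect_true(all(is.na(s$group_table$p_recovery_vs_rest)))
  expect_true(all(is.na(s$group_table$p_mpri_recov_vs_rest)))
  expect_equal(s$group_table$mpri_rest_sd, c(0, 0))
  # single group: no between-group table, within-group rows still present
  single <- res[res$group == "none", ]
  s1 <- summarize_cohort(single)
  expect_null(s1$between)
  expect_equal(nrow(s1$group_table), 1)
  expect_error(summarize_cohort(res[1, ]), class = "mpri_insufficient_data_error")
  dup <- res; dup$id[2] <- dup$id[1]
  expect_error(summarize_cohort(dup), class = "mpri_input_error")
})
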