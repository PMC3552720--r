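# Shared fixtures, built in code at test time.

# Noise-free default phantom configuration.
quiet_config <- function(...) {
  phantom_config(noise_sd = 0, ...)
}

# Independent brute-force maximum up-slope: enumerate every window between
# foot and the global peak and fit with stats::lsfit. Deliberately naive, used
# as the oracle for max_upslope.
brute_force_max_upslope <- function(curve, window_len = 3L, k_baseline = 5L,
                                    threshold_sd = 2) {
  bf <- estimate_baseline_foot(curve, k_baseline, threshold_sd)
  peak <- which.max(curve$value)
  foot_pos <- match(TRUE, curve$frame >= bf$foot)
  best <- -Inf
  for (s in foot_pos:(peak - window_len + 1L)) {
    idx <- s:(s + window_len - 1L)
    co <- stats::lsfit(curve$frame[idx], curve$value[idx])$coefficients
    if (co[2] > best) best <- unname(co[2])
  }
  best
}

# Independent two-sided Fisher p by exhaustive hypergeometric enumeration
# (point-probability method).
enumerate_fisher_p <- function(tab) {
  m <- rowSums(tab); n <- colSums(tab)
  xs <- max(0, n[1] - m[2]):min(m[1], n[1])
  probs <- stats::dhyper(xs, m[1], m[2], n[1])
  obs <- stats::dhyper(tab[1, 1], m[1], m[2], n[1])
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Random first-pass-like curve: flat baseline, then a noisy sigmoid rise to a
# peak, then partial washout. Guaranteed analyzable (>= 10 frames, clear rise).
random_first_pass_curve <- function(n = 30L) {
  t0 <- sample(5:8, 1)
  amp <- stats::runif(1, 20, 200)
  width <- stats::runif(1, 1.5, 4)
  t <- 0:(n - 1)
  v <- amp / (1 + exp(-(t - t0 - 2 * width) / width))
  v <- v + stats::rnorm(n, sd = amp * 0.01)
  v[seq_len(t0)] <- v[seq_len(t0)] + stats::rnorm(t0, sd = amp * 0.002)
  tic(t, v, region = "random")
}

# Cohort results fixture with constant per-subject values.
constant_cohort_results <- function(n_per_group = 5, mpri_rest = 2,
                                    mpri_recov = 1.5) {
  df <- data.frame(
    id = sprintf("S%02d", seq_len(2 * n_per_group)),
    group = rep(c("aminophylline", "none"), each = n_per_group),
    rest = 8, stress = 8 * mpri_rest, recovery = 8 * mpri_rest / mpri_recov,
    mpri_rest = mpri_rest, mpri_recov = mpri_recov,
    pct_reduction = 100 * (mpri_rest - mpri_recov) / mpri_rest,
    delayed = FALSE,
    stringsAsFactors = FALSE
  )
  df
}
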