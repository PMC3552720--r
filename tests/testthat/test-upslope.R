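test_that("baseline and foot follow their construction", {
  # 10 flat frames at 100, then a ramp; k_baseline = 8
  curve <- tic(0:24, c(rep(100, 10), 100 + 5 * (1:15)))
  bf <- estimate_baseline_foot(curve, k_baseline = 8)
  expect_equal(bf$baseline, 100)
  expect_equal(bf$foot, 9)

  expect_error(estimate_baseline_foot(tic(0:19, rep(5, 20))),
               class = "mpri_no_enhancement_error")
  expect_error(estimate_baseline_foot(curve, k_baseline = 2),
               class = "mpri_parameter_error")
})

test_that("foot detection lands within two frames of the true contrast arrival under noise", {
  # noise ~1% of the cavity peak; arrival = onset (frame 5) + short transit
  feet <- vapply(1:40, function(s) {
    sub <- simulate_subject(phantom_config(noise_sd = 1.1, seed = s),
                            render = FALSE)
    max_upslope(sub$states$rest$curves$anterior)$foot
  }, numeric(1))
  expect_true(all(feet >= 4 & feet <= 8))
})

test_that("an exact ramp yields its slope for any window length", {
  curve <- tic(0:19, c(rep(0, 8), 4 * (1:12)))
  for (w in c(2L, 3L, 5L)) {
    est <- max_upslope(curve, window_len = w)
    expect_equal(est$slope, 4)
  }
  expect_error(max_upslope(tic(0:19, rep(1, 20))),
               class = "mpri_no_enhancement_error")
})

test_that("piecewise-linear rises report the steepest segment", {
  # slopes 1, then 5, then 2; each segment >= window length
  v <- c(rep(0, 6), cumsum(c(rep(1, 5), rep(5, 5), rep(2, 5))))
  curve <- tic(seq_along(v) - 1, v)
  est <- max_upslope(curve, window_len = 3L)
  expect_equal(est$slope, 5)
  expect_equal(brute_force_max_upslope(curve), 5)
})

test_that("max_upslope agrees with brute-force window search on random curves", {
  set.seed(101)
  for (i in 1:300) {
    curve <- random_first_pass_curve()
    est <- tryCatch(max_upslope(curve), mpri_error = function(e) NULL)
    if (is.null(est)) next
    expect_equal(est$slope, brute_force_max_upslope(curve), tolerance = 1e-10)
  }
})

test_that("ties between equal-slope windows go to the earliest window", {
  curve <- tic(0:14, c(rep(0, 5), 2 * (0:9)))  # constant slope after the foot
  est <- max_upslope(curve, window_len = 3L)
  expect_equal(est$window_start, est$foot)
})

test_that("normalization scales by the blood slope and averages sectors", {
  mk <- function(slope, region) {
    structure(list(slope = slope, window_start = 6, window_end = 8,
                   intercept = 0, r2 = 1, baseline = 0, baseline_sd = 0,
                   foot = 5, region = region, state = "rest"),
              class = "upslope_estimate")
  }
  sectors <- lapply(c("anterior", "lateral", "inferior", "septal"), mk,
                    slope = 1)
  blood <- mk(10, "blood")
  ns <- normalize_upslopes(sectors, blood)
  expect_equal(unname(ns$sector_values), rep(10, 4))
  expect_equal(ns$mean, 10)

  ratio <- normalize_upslopes(sectors, blood, times100 = FALSE)
  expect_equal(ns$mean, 100 * ratio$mean)
  expect_error(normalize_upslopes(sectors, mk(0, "blood")),
               class = "mpri_normalization_error")
  expect_error(normalize_upslopes(sectors, mk(-2, "blood")),
               class = "mpri_normalization_error")
})

test_that("normalize-then-average equals average-then-normalize", {
  set.seed(7)
  for (i in 1:20) {
    slopes <- stats::runif(4, 0.1, 3)
    blood_slope <- stats::runif(1, 5, 20)
    mk <- function(s, r) structure(
      list(slope = s, window_start = 6, window_end = 8, intercept = 0, r2 = 1,
           baseline = 0, baseline_sd = 0, foot = 5, region = r, state = "x"),
      class = "upslope_estimate")
    sectors <- Map(mk, slopes, paste0("s", 1:4))
    blood <- mk(blood_slope, "blood")
    ns <- normalize_upslopes(sectors, blood)
    expect_equal(ns$mean, 100 * mean(slopes) / blood_slope)
  }
})

test_that("per-state gain changes leave normalized up-slopes unchanged", {
  cfg <- quiet_config()
  sub <- simulate_subject(cfg, render = FALSE)
  curves <- sub$states$rest$curves
  base <- analyze_state_curves(curves)$normalized
  for (g in c(0.25, 3.7)) {
    scaled <- lapply(curves, function(cu) tic(cu$frame, g * cu$value,
                                              cu$region, cu$state))
    got <- analyze_state_curves(scaled)$normalized
    expect_equal(got$sector_values, base$sector_values)
    expect_equal(got$mean, base$mean)
  }
})

test_that("adding a constant offset changes no slope", {
  cfg <- quiet_config()
  sub <- simulate_subject(cfg, render = FALSE)
  curve <- sub$states$stress$curves$lateral
  est <- max_upslope(curve)
  shifted <- tic(curve$frame, curve$value + 57.3, curve$region, curve$state)
  est2 <- max_upslope(shifted)
  expect_equal(est2$slope, est$slope)
  expect_equal(est2$window_start, est$window_start)
})

test_that("normalized up-slope increases strictly with true flow", {
  mults <- c(1, 1.4, 1.8, 2.2, 2.6, 3)
  vals <- vapply(mults, function(m) {
    states <- if (m == 1) default_states() else
      default_states(stress_multiplier = m)
    cfg <- quiet_config(states = states)
    sub <- simulate_subject(cfg, render = FALSE)
    st <- if (m == 1) "rest" else "stress"
    analyze_state_curves(sub$states[[st]]$curves)$normalized$mean
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the optional moving-average smoother preserves a clean ramp's slope", {
  curve <- tic(0:19, c(rep(0, 8), 4 * (1:12)))
  expect_equal(max_upslope(curve, smooth = TRUE)$slope, 4, tolerance = 1e-12)
})
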