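test_that("gamma-variate input is zero up to onset, peaks at A, and is linear in A", {
  p <- aif_params(t0 = 5, alpha = 3, beta = 2, A = 100)
  aif <- gamma_variate_aif(p, 40)
  expect_equal(aif$value[aif$frame <= 5], rep(0, 6))
  # analytic peak: t = t0 + alpha * beta = 11, value A
  expect_equal(aif$value[aif$frame == 11], 100)
  expect_equal(max(aif$value), 100)
  expect_true(all(aif$value >= 0))
  doubled <- gamma_variate_aif(aif_params(t0 = 5, alpha = 3, beta = 2, A = 200), 40)
  expect_equal(doubled$value, 2 * aif$value)
})

test_that("gamma-variate rejects out-of-range parameters", {
  expect_error(aif_params(alpha = 0), class = "mpri_parameter_error")
  expect_error(aif_params(beta = -1), class = "mpri_parameter_error")
  expect_error(aif_params(t0 = -2), class = "mpri_parameter_error")
  expect_error(aif_params(A = NaN), class = "mpri_parameter_error")
  expect_error(gamma_variate_aif(aif_params(), 0), class = "mpri_parameter_error")
})

test_that("tissue model: no inflow gives a flat curve, large partition gives the cumulative integral", {
  aif <- gamma_variate_aif(aif_params(), 50)
  zero <- kety_tissue_curve(aif, kinetic_params(flow = 0, partition = 1))
  expect_equal(zero$value, rep(0, 50))

  F <- 0.04
  no_washout <- kety_tissue_curve(aif, kinetic_params(flow = F, partition = 1e9))
  # independent trapezoidal cumulative integral of the input
  trapz <- c(0, cumsum((aif$value[-1] + aif$value[-50]) / 2))
  rel <- abs(no_washout$value[-(1:6)] - F * trapz[-(1:6)]) / (F * trapz[-(1:6)])
  expect_lt(max(rel), 0.001)
  expect_error(kinetic_params(flow = -1), class = "mpri_parameter_error")
})

test_that("doubling flow doubles the maximum up-slope to within 2.5%", {
  aif <- gamma_variate_aif(aif_params(), 50)
  kin <- kinetic_params()
  s1 <- max_upslope(kety_tissue_curve(aif, kin))$slope
  s2 <- max_upslope(kety_tissue_curve(aif, kinetic_params(2 * kin$flow, kin$partition)))$slope
  expect_gt(s2 / s1, 1.95)
  expect_lt(s2 / s1, 2.05)
})

test_that("rendered frames reproduce the generating curves exactly without noise", {
  cfg <- quiet_config()
  st <- cfg$states$rest
  r <- render_phantom_series(cfg, st)
  aif <- gamma_variate_aif(cfg$aif, cfg$n_frames)
  cav_means <- apply(r$series, 3, function(fr) mean(fr[r$mask$cavity]))
  expect_equal(cav_means, st$baseline_offset + st$signal_gain * aif$value)
  myo_means <- apply(r$series, 3, function(fr) mean(fr[r$mask$myocardium]))
  tissue <- kety_tissue_curve(aif, cfg$kinetics)
  expect_equal(myo_means, st$baseline_offset + st$signal_gain * tissue$value)
})

test_that("rendering is deterministic under a fixed seed and masks partition the grid", {
  cfg <- phantom_config(noise_sd = 2, seed = 11L)
  a <- render_phantom_series(cfg, cfg$states$stress)
  b <- render_phantom_series(cfg, cfg$states$stress)
  expect_identical(a$series, b$series)
  m <- a$mask
  background <- !m$cavity & !m$myocardium
  expect_false(any(m$cavity & m$myocardium))
  expect_true(all(m$cavity | m$myocardium | background))
  expect_equal(sum(m$cavity) + sum(m$myocardium) + sum(background),
               prod(m$dim))
})

test_that("degenerate geometry raises a configuration error", {
  expect_error(phantom_config(cavity_radius = 0.1, r_inner = 0.2, r_outer = 0.3),
               class = "mpri_config_error")
})

test_that("subject truth records flows, MPR, recovery ratio and the delayed flag", {
  cfg <- quiet_config(states = default_states(stress_multiplier = 2.0,
                                              recovery_multiplier = 1.68))
  sub <- simulate_subject(cfg, render = FALSE)
  expect_equal(sub$truth$true_mpr, 2.0)
  expect_equal(sub$truth$recovery_to_rest, 1.68)
  expect_false(sub$truth$delayed)
  expect_equal(sub$truth$flow$stress / sub$truth$flow$rest, 2.0)

  delayed_cfg <- quiet_config(states = default_states(stress_multiplier = 1.4,
                                                      recovery_multiplier = 1.8))
  d <- simulate_subject(delayed_cfg, render = FALSE)
  expect_true(d$truth$flow$recovery > d$truth$flow$stress)
  expect_true(d$truth$delayed)
})

test_that("identical multipliers and zero noise give identical state datasets", {
  cfg <- quiet_config(states = default_states(stress_multiplier = 1,
                                              recovery_multiplier = 1))
  sub <- simulate_subject(cfg, render = FALSE)
  expect_equal(sub$states$stress$curves$blood$value,
               sub$states$rest$curves$blood$value)
  expect_equal(sub$states$recovery$curves$anterior$value,
               sub$states$rest$curves$anterior$value)
})

test_that("the rest state must not rescale flow", {
  expect_error(state_config("rest", flow_multiplier = 1.5),
               class = "mpri_parameter_error")
})

test_that("cohort simulation honors group counts and delayed assignments exactly", {
  spec <- make_group_spec(n_amino = 10, n_none = 10,
                          delayed_amino = 4, delayed_none = 3)
  coh <- simulate_cohort(spec, phantom_config(noise_sd = 1), seed = 7)
  expect_equal(nrow(coh$index), 20)
  expect_equal(sum(coh$index$group == "aminophylline"), 10)
  expect_equal(sum(coh$index$delayed[coh$index$group == "aminophylline"]), 4)
  expect_equal(sum(coh$index$delayed[coh$index$group == "none"]), 3)
  # the delayed truth ordering holds subject by subject
  for (s in coh$subjects) {
    expect_identical(s$truth$delayed, s$delayed)
  }
})

test_that("zero jitter reproduces the base truth; same seed reproduces the cohort", {
  spec <- make_group_spec(n_amino = 0, n_none = 4, delayed_amino = 0,
                          delayed_none = 0)
  base <- quiet_config()
  coh <- simulate_cohort(spec, base, seed = 3, flow_sdlog = 0, mult_sdlog = 0)
  base_truth <- simulate_subject(base, render = FALSE)$truth
  for (s in coh$subjects) {
    expect_equal(s$truth$true_mpr, base_truth$true_mpr)
    expect_equal(s$truth$recovery_to_rest, base_truth$recovery_to_rest)
    expect_equal(s$truth$flow$rest, base_truth$flow$rest)
  }
  coh2 <- simulate_cohort(spec, base, seed = 3, flow_sdlog = 0, mult_sdlog = 0)
  expect_identical(coh$index, coh2$index)
  expect_equal(coh$subjects[[2]]$states$rest$curves$blood$value,
               coh2$subjects[[2]]$states$rest$curves$blood$value)
  expect_error(simulate_cohort(data.frame()), class = "mpri_config_error")
})

test_that("noise-free up-slope ratios recover true flow ratios within 10% across [1, 3]", {
  norm_mean <- function(mult) {
    cfg <- quiet_config(states = default_states(stress_multiplier = mult,
                                                recovery_multiplier = 1.1))
    sub <- simulate_subject(cfg, render = FALSE)
    analyze_state_curves(sub$states$stress$curves)$normalized$mean
  }
  base <- {
    cfg <- quiet_config()
    sub <- simulate_subject(cfg, render = FALSE)
    analyze_state_curves(sub$states$rest$curves)$normalized$mean
  }
  for (mult in c(1.2, 2, 3)) {
    est <- norm_mean(mult) / base
    expect_lt(abs(est - mult) / mult, 0.10)
  }
})
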