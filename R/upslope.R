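# Semi-quantitative up-slope analysis: pre-contrast baseline and arrival-foot
# detection, sliding-window least-squares maximum up-slope, and normalization
# of myocardial up-slopes to the LV cavity (blood pool) up-slope. The
# normalization cancels injection, contrast-dose and receiver-gain effects, so
# the normalized up-slope is the flow surrogate that perfusion reserve indices
# are built from.

#' Baseline level and contrast-arrival foot of a curve
#'
#' The baseline is the mean (and SD) of the first `k_baseline` frames. The
#' foot is the frame just before the first frame whose value exceeds
#' `baseline + threshold_sd * baseline SD`, clamped to frame 0.
#'
#' @param curve A [tic()] with at least `k_baseline + 1` frames.
#' @param k_baseline Number of leading pre-contrast frames (>= 3).
#' @param threshold_sd Detection threshold in baseline SDs.
#' @return List with `baseline`, `baseline_sd`, `foot` (0-based frame index).
#' @export
estimate_baseline_foot <- function(curve, k_baseline = 5L, threshold_sd = 2) {
  check_analysis_curve(curve)
  check_scalar(k_baseline, "k_baseline", lower = 3, integer = TRUE)
  check_scalar(threshold_sd, "threshold_sd", lower = 0)
  if (length(curve$frame) <= k_baseline)
    input_error("curve must be longer than the baseline window")
  base_vals <- curve$value[seq_len(k_baseline)]
  baseline <- mean(base_vals)
  baseline_sd <- stats::sd(base_vals)
  thr <- baseline + threshold_sd * baseline_sd
  above <- which(curve$value > thr)
  if (length(above) == 0L)
    no_enhancement_error(sprintf(
      "no frame of region '%s' exceeds the baseline threshold (flat curve?)",
      curve$region))
  list(baseline = baseline, baseline_sd = baseline_sd,
       foot = max(curve$frame[above[1L]] - 1, 0))
}

#' Maximum up-slope of a time-intensity curve
#'
#' Fits ordinary least squares lines to every contiguous window of
#' `window_len` frames starting at or after the contrast-arrival foot and
#' ending no later than the curve's global maximum (the first-pass peak, so
#' recirculation never enters the fit), and returns the window with the
#' largest slope; ties go to the earliest window.
#'
#' @param curve A [tic()].
#' @param window_len Frames per fitted window (>= 2; default 3, the minimum
#'   leaving a residual degree of freedom).
#' @param k_baseline,threshold_sd Passed to [estimate_baseline_foot()].
#' @param smooth If `TRUE`, apply a 3-point moving average before fitting
#'   (off by default).
#' @return An object of class `upslope_estimate`: `slope` (signal units per
#'   heartbeat), `window_start`/`window_end` (0-based frames, inclusive),
#'   `intercept`, `r2`, `baseline`, `baseline_sd`, `foot`, `region`, `state`.
#' @examples
#' ramp <- tic(0:19, c(rep(0, 8), (1:12) * 4))
#' max_upslope(ramp)$slope  # 4
#' @export
max_upslope <- function(curve, window_len = 3L, k_baseline = 5L,
                        threshold_sd = 2, smooth = FALSE) {
  check_analysis_curve(curve)
  check_scalar(window_len, "window_len", lower = 2, integer = TRUE)
  if (isTRUE(smooth)) {
    v <- curve$value
    sm <- v
    n <- length(v)
    if (n >= 3L) sm[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
    curve <- tic(curve$frame, sm, curve$region, curve$state)
  }
  bf <- estimate_baseline_foot(curve, k_baseline, threshold_sd)
  peak_pos <- which.max(curve$value)
  foot_pos <- match(TRUE, curve$frame >= bf$foot)
  n_windows <- peak_pos - window_len + 1L - (foot_pos - 1L)
  if (is.na(foot_pos) || n_windows < 1L)
    insufficient_rise_error(sprintf(
      "region '%s': fewer than %d frames between foot (frame %g) and peak (frame %g)",
      curve$region, window_len, bf$foot, curve$frame[peak_pos]))
  best <- NULL
  for (s in foot_pos:(peak_pos - window_len + 1L)) {
    idx <- s:(s + window_len - 1L)
    fit <- ols_line(curve$frame[idx], curve$value[idx])
    if (is.null(best) || fit$slope > best$slope) {
      best <- fit
      best$window <- idx
    }
  }
  structure(
    list(slope = best$slope, window_start = curve$frame[best$window[1L]],
         window_end = curve$frame[best$window[window_len]],
         intercept = best$intercept, r2 = best$r2,
         baseline = bf$baseline, baseline_sd = bf$baseline_sd, foot = bf$foot,
         region = curve$region, state = curve$state),
    class = "upslope_estimate"
  )
}

# Closed-form simple linear regression with R^2.
ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum((y - (intercept + slope * x))^2) / ss_tot
  list(slope = slope, intercept = intercept, r2 = r2)
}

#' @export
print.upslope_estimate <- function(x, ...) {
  cat(sprintf("<up-slope> region=%s state=%s slope=%.4g/beat window=[%g,%g] r2=%.3f foot=%g\n",
              x$region, x$state, x$slope, x$window_start, x$window_end, x$r2,
              x$foot))
  invisible(x)
}

#' Normalize myocardial up-slopes to the blood-pool up-slope
#'
#' Each sector's maximum up-slope is divided by the LV cavity (blood pool)
#' up-slope; by default the ratio is reported x100 so that healthy resting
#' values land near 8 and stress values near 14. The set mean is the
#' arithmetic mean of the sector values, which (all sectors sharing the same
#' positive denominator) is identical to normalizing the mean myocardial
#' up-slope.
#'
#' @param sector_estimates List of `upslope_estimate`s, one per sector.
#' @param blood The blood-pool `upslope_estimate` (slope must be positive).
#' @param times100 Report percentages of the blood-pool up-slope (default) or
#'   pure ratios.
#' @return An object of class `normalized_upslope_set`: `sector_values`
#'   (named), `mean`, `blood_slope`, `state`, `scale`.
#' @export
normalize_upslopes <- function(sector_estimates, blood, times100 = TRUE) {
  if (length(sector_estimates) < 1L)
    input_error("at least one sector up-slope is required")
  stopifnot(inherits(blood, "upslope_estimate"))
  if (!is.finite(blood$slope) || blood$slope <= 0)
    normalization_error(sprintf(
      "blood-pool up-slope must be positive (got %g)", blood$slope))
  scale <- if (isTRUE(times100)) 100 else 1
  vals <- vapply(sector_estimates, function(e) {
    stopifnot(inherits(e, "upslope_estimate"))
    scale * e$slope / blood$slope
  }, numeric(1))
  names(vals) <- vapply(sector_estimates, `[[`, character(1), "region")
  structure(
    list(sector_values = vals, mean = mean(vals), blood_slope = blood$slope,
         state = blood$state, scale = scale),
    class = "normalized_upslope_set"
  )
}

#' @export
print.normalized_upslope_set <- function(x, ...) {
  cat(sprintf("<normalized up-slopes> state=%s mean=%.3f (x%g)\n",
              x$state, x$mean, x$scale))
  print(round(x$sector_values, 3))
  invisible(x)
}

#' Up-slope analysis of one state's curve set
#'
#' Runs [max_upslope()] on the blood curve and every sector curve, then
#' [normalize_upslopes()].
#'
#' @param curves Named list with `blood` plus sector curves (from
#'   [extract_state_curves()] or read from CSV).
#' @param window_len,k_baseline,threshold_sd,smooth Analysis parameters, see
#'   [max_upslope()].
#' @param times100 See [normalize_upslopes()].
#' @return List with `normalized` (a `normalized_upslope_set`) and `estimates`
#'   (all per-region `upslope_estimate`s, blood first).
#' @export
analyze_state_curves <- function(curves, window_len = 3L, k_baseline = 5L,
                                 threshold_sd = 2, smooth = FALSE,
                                 times100 = TRUE) {
  if (!"blood" %in% names(curves))
    input_error("curve set must contain a 'blood' curve")
  ests <- lapply(curves, max_upslope, window_len = window_len,
                 k_baseline = k_baseline, threshold_sd = threshold_sd,
                 smooth = smooth)
  sectors <- ests[setdiff(names(ests), "blood")]
  list(normalized = normalize_upslopes(sectors, ests$blood, times100),
       estimates = ests)
}
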