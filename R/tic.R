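#' Time-intensity curve
#'
#' A region-mean signal trace over the dynamic acquisition. Frame indices are
#' 0-based heartbeat counts (one frame per heartbeat), so slopes computed from
#' these curves are in signal units per heartbeat.
#'
#' @param frame Integer vector of 0-based frame indices, strictly increasing.
#' @param value Numeric vector of mean signal intensities, same length.
#' @param region Region label, e.g. `"blood"`, `"anterior"`.
#' @param state Physiologic state label: `"rest"`, `"stress"` or `"recovery"`
#'   (or `NA` when not tied to a state).
#' @return An object of class `tic`: a list with elements `frame`, `value`,
#'   `region`, `state`.
#' @examples
#' tc <- tic(0:9, c(rep(1, 5), 2, 4, 6, 8, 10), region = "blood")
#' as.data.frame(tc)
#' @export
tic <- function(frame, value, region = NA_character_, state = NA_character_) {
  if (length(frame) != length(value))
    input_error("'frame' and 'value' must have equal length")
  if (length(frame) < 1L)
    input_error("a time-intensity curve needs at least one frame")
  if (any(!is.finite(frame)) || any(diff(frame) <= 0))
    input_error("'frame' must be finite and strictly increasing")
  if (any(frame < 0))
    input_error("'frame' indices are 0-based and must be non-negative")
  if (any(!is.finite(value)))
    input_error("'value' must be finite")
  structure(
    list(frame = as.numeric(frame), value = as.numeric(value),
         region = as.character(region), state = as.character(state)),
    class = "tic"
  )
}

#' @export
as.data.frame.tic <- function(x, ...) {
  data.frame(frame = x$frame, value = x$value,
             region = x$region, state = x$state,
             stringsAsFactors = FALSE)
}

#' @export
length.tic <- function(x) length(x$frame)

#' @export
print.tic <- function(x, ...) {
  cat(sprintf("<time-intensity curve> region=%s state=%s, %d frames, range [%.3g, %.3g]\n",
              x$region, x$state, length(x$frame), min(x$value), max(x$value)))
  invisible(x)
}

# Minimum curve length demanded by the analysis operations (baseline + rise).
MIN_ANALYSIS_FRAMES <- 10L

check_analysis_curve <- function(curve) {
  if (!inherits(curve, "tic"))
    input_error("expected a 'tic' time-intensity curve")
  if (length(curve$frame) < MIN_ANALYSIS_FRAMES)
    input_error(sprintf("analysis needs at least %d frames, got %d",
                        MIN_ANALYSIS_FRAMES, length(curve$frame)))
  invisible(curve)
}
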