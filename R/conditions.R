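# Classed conditions so callers (and the CLI) can map failure modes to exit
# codes without parsing messages.

mpri_error <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "mpri_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

parameter_error <- function(msg, ...) mpri_error("mpri_parameter_error", msg, ...)
geometry_error <- function(msg, ...) mpri_error("mpri_geometry_error", msg, ...)
config_error <- function(msg, ...) mpri_error("mpri_config_error", msg, ...)
input_error <- function(msg, ...) mpri_error("mpri_input_error", msg, ...)
io_error <- function(msg, ...) mpri_error("mpri_io_error", msg, ...)
domain_error <- function(msg, ...) mpri_error("mpri_domain_error", msg, ...)
no_enhancement_error <- function(msg, ...) mpri_error("mpri_no_enhancement_error", msg, ...)
insufficient_rise_error <- function(msg, ...) mpri_error("mpri_insufficient_rise_error", msg, ...)
normalization_error <- function(msg, ...) mpri_error("mpri_normalization_error", msg, ...)
zero_variance_error <- function(msg, ...) mpri_error("mpri_zero_variance_error", msg, ...)
insufficient_data_error <- function(msg, ...) mpri_error("mpri_insufficient_data_error", msg, ...)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    parameter_error(sprintf("'%s' must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    parameter_error(sprintf("'%s' = %g is outside its valid range", name, x))
  if (integer && x != round(x))
    parameter_error(sprintf("'%s' must be an integer", name))
  invisible(x)
}
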