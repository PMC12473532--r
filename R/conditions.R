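# Classed conditions so callers can distinguish configuration mistakes from
# transient signal-quality problems (which mark data invalid rather than abort).

mv_abort <- function(class, message, ...) {
  stop(structure(
    class = c(class, "mirrorvitals_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

abort_config <- function(message, ...) mv_abort("mv_config_error", message, ...)
abort_signal_quality <- function(message, ...) mv_abort("mv_signal_quality_error", message, ...)
abort_stream <- function(message, ...) mv_abort("mv_stream_error", message, ...)
abort_geometry <- function(message, ...) mv_abort("mv_geometry_error", message, ...)
abort_classification <- function(message, ...) mv_abort("mv_classification_error", message, ...)
abort_context <- function(message, ...) mv_abort("mv_context_error", message, ...)
abort_chat <- function(message, ...) mv_abort("mv_chat_error", message, ...)
abort_io <- function(message, ...) mv_abort("mv_io_error", message, ...)
abort_parse <- function(message, ...) mv_abort("mv_parse_error", message, ...)
abort_alignment <- function(message, ...) mv_abort("mv_alignment_error", message, ...)
abort_empty_input <- function(message, ...) mv_abort("mv_empty_input_error", message, ...)

stopifnot_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_config(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    abort_config(sprintf("`%s` must be > 0 (got %g)", name, x))
  if (nonneg && x < 0)
    abort_config(sprintf("`%s` must be >= 0 (got %g)", name, x))
  invisible(x)
}
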