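# Classed conditions used across the package so callers (and tests) can
# distinguish failure modes programmatically.

qm_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "quenchmap_error"), ...)
}

abort_format <- function(message, ...) qm_abort(message, "qm_format_error", ...)
abort_incomplete_trace <- function(message, ...) qm_abort(message, "qm_incomplete_trace_error", ...)
abort_value <- function(message, ...) qm_abort(message, "qm_value_error", ...)
abort_config <- function(message, ...) qm_abort(message, "qm_config_error", ...)
abort_merge <- function(message, ...) qm_abort(message, "qm_merge_error", ...)
abort_pairing <- function(message, ...) qm_abort(message, "qm_pairing_error", ...)
abort_degenerate <- function(message, ...) qm_abort(message, "qm_degenerate_error", ...)
abort_insufficient_data <- function(message, ...) qm_abort(message, "qm_insufficient_data_error", ...)
abort_fit_failure <- function(message, ...) qm_abort(message, "qm_fit_failure_error", ...)
abort_no_extremum <- function(message, ...) qm_abort(message, "qm_no_extremum_error", ...)
abort_unstable_fit <- function(message, ...) qm_abort(message, "qm_unstable_fit_error", ...)
abort_io <- function(message, ...) qm_abort(message, "qm_io_error", ...)

qm_warn <- function(message, class) {
  rlang::warn(message, class = c(class, "quenchmap_warning"))
}
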