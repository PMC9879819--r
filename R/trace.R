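#' A single well's saturating-pulse trace
#'
#' Holds the dark-adapted reference measurement (F0, Fm; pulse 0) and the
#' ordered saturating-pulse readings (F, Fm') with phase labels.  Under the
#' default protocol pulses 1-5 are taken in actinic light and pulses 6-10 in
#' the subsequent dark recovery, matching the subscripts Fm'5 and Fm'6-10
#' used by the deconvolution equations.
#'
#' @param well Well address, e.g. `"A1"`.
#' @param f0 Minimal dark-adapted fluorescence (a.u., >= 0).
#' @param fm Maximum dark-adapted fluorescence (a.u., > 0).
#' @param pulses A data frame with columns `index` (1..n), `time_s` (strictly
#'   increasing), `f` (>= 0), `fm_prime` (> 0) and `phase`
#'   (`"light"`/`"dark"`, all light pulses before all dark pulses).
#'
#' @return An object of class `pulse_trace`.
#' @export
pulse_trace <- function(well, f0, fm, pulses) {
  validate_well(well)
  if (!is.finite(fm) || fm <= 0) abort_value(sprintf("Well %s: Fm must be > 0.", well))
  if (!is.finite(f0) || f0 < 0) abort_value(sprintf("Well %s: F0 must be >= 0.", well))
  pulses <- tibble::as_tibble(pulses)
  req <- c("index", "time_s", "f", "fm_prime", "phase")
  miss <- setdiff(req, names(pulses))
  if (length(miss) > 0) {
    abort_format(sprintf("Pulse table for well %s missing column(s): %s",
                         well, paste(miss, collapse = ", ")))
  }
  pulses <- pulses[order(pulses$index), req]
  if (!identical(as.integer(pulses$index), seq_len(nrow(pulses)))) {
    abort_value(sprintf("Well %s: pulse indices must be 1..%d.", well, nrow(pulses)))
  }
  if (any(diff(pulses$time_s) <= 0)) {
    abort_value(sprintf("Well %s: pulse times must be strictly increasing.", well))
  }
  bad <- which(!is.finite(pulses$fm_prime) | pulses$fm_prime <= 0)
  if (length(bad) > 0) {
    abort_value(sprintf("Well %s: non-positive Fm' at pulse(s) %s.",
                        well, paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(pulses$f) | pulses$f < 0)) {
    abort_value(sprintf("Well %s: F readings must be >= 0.", well))
  }
  if (!all(pulses$phase %in% c("light", "dark"))) {
    abort_value(sprintf("Well %s: phase must be 'light' or 'dark'.", well))
  }
  ph <- pulses$phase
  n_light <- sum(ph == "light")
  if (!identical(ph, c(rep("light", n_light), rep("dark", nrow(pulses) - n_light)))) {
    abort_value(sprintf("Well %s: all light pulses must precede all dark pulses.", well))
  }
  structure(
    list(well = well, f0 = f0, fm = fm, pulses = pulses,
         n_light = n_light, n_dark = nrow(pulses) - n_light),
    class = "pulse_trace"
  )
}

#' @export
print.pulse_trace <- function(x, ...) {
  cat(sprintf("<pulse_trace> well %s: F0 = %.4g, Fm = %.4g, %d light + %d dark pulses\n",
              x$well, x$f0, x$fm, x$n_light, x$n_dark))
  invisible(x)
}

check_trace_pulses <- function(trace, protocol) {
  n_exp <- protocol$n_light_pulses + protocol$n_dark_pulses
  if (nrow(trace$pulses) != n_exp || trace$n_light != protocol$n_light_pulses) {
    abort_incomplete_trace(sprintf(
      "Well %s has %d pulses (%d light); protocol implies %d (%d light).",
      trace$well, nrow(trace$pulses), trace$n_light, n_exp, protocol$n_light_pulses))
  }
  invisible(trace)
}

#' A full plate measurement
#'
#' A set of [pulse_trace()] objects keyed by well address plus the run
#' metadata: the measurement protocol, the gradient identifier, the per-well
#' temperature map, whether far-red light was on during dark recovery, and
#' the acclimation history of the cultures (growth temperature 19/26/29 deg C,
#' light level `"LL"` or `"HL"`).
#'
#' @param protocol A [protocol_spec()].
#' @param traces Named list of [pulse_trace()] objects (names = well
#'   addresses, matching each trace's own `well`).
#' @param gradient_id Label identifying the temperature gradient of this run.
#' @param well_temperature Optional named numeric vector (names = wells) of
#'   temperatures in deg C; usually set later via [assign_temperatures()].
#' @param fr_in_dark Logical; far-red on during dark recovery.
#' @param acclimation List with `growth_temperature` (19, 26 or 29) and
#'   `light_level` (`"LL"` or `"HL"`).
#'
#' @return An object of class `plate_run`.
#' @export
plate_run <- function(protocol, traces, gradient_id = "g1",
                      well_temperature = NULL, fr_in_dark = FALSE,
                      acclimation = list(growth_temperature = 26, light_level = "LL")) {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (length(traces) == 0) abort_value("A plate run needs at least one trace.")
  wells <- vapply(traces, function(tr) tr$well, character(1))
  if (is.null(names(traces))) names(traces) <- wells
  if (!identical(unname(names(traces)), unname(wells))) {
    abort_value("Trace list names must equal the traces' well addresses.")
  }
  if (anyDuplicated(wells)) abort_value("Duplicated well addresses in traces.")
  for (tr in traces) check_trace_pulses(tr, protocol)
  if (!is.null(well_temperature)) {
    check_well_temperatures(well_temperature, wells)
  }
  if (!acclimation$growth_temperature %in% c(19, 26, 29)) {
    abort_value("acclimation$growth_temperature must be 19, 26 or 29.")
  }
  if (!acclimation$light_level %in% c("LL", "HL")) {
    abort_value("acclimation$light_level must be 'LL' or 'HL'.")
  }
  structure(
    list(protocol = protocol, traces = traces, gradient_id = gradient_id,
         well_temperature = well_temperature, fr_in_dark = isTRUE(fr_in_dark),
         acclimation = acclimation),
    class = "plate_run"
  )
}

check_well_temperatures <- function(well_temperature, wells) {
  miss <- setdiff(wells, names(well_temperature))
  if (length(miss) > 0) {
    abort_value(sprintf("No temperature for well(s): %s", paste(miss, collapse = ", ")))
  }
  temps <- well_temperature[wells]
  if (any(!is.finite(temps)) || any(temps < 10 - 1e-9) || any(temps > 45 + 1e-9)) {
    abort_value("Well temperatures must lie within 10-45 deg C.")
  }
  # temperatures within a column must be identical
  cols <- well_col(wells)
  for (cc in unique(cols)) {
    tc <- temps[cols == cc]
    if (diff(range(tc)) > 1e-9) {
      abort_value(sprintf("Column %d carries unequal temperatures.", cc))
    }
  }
  invisible(well_temperature)
}

#' @export
print.plate_run <- function(x, ...) {
  cat(sprintf("<plate_run> %s: %d wells, %s/%g C acclimation, far-red in dark: %s\n",
              x$gradient_id, length(x$traces),
              x$acclimation$light_level, x$acclimation$growth_temperature,
              if (x$fr_in_dark) "on" else "off"))
  if (!is.null(x$well_temperature)) {
    cat(sprintf("  temperatures: %.1f-%.1f C\n",
                min(x$well_temperature), max(x$well_temperature)))
  } else {
    cat("  temperatures: not assigned\n")
  }
  invisible(x)
}
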