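#' Measurement protocol specification
#'
#' Describes the saturating-pulse measurement protocol: a far-red
#' pre-illumination of the dark-adapted sample, an actinic light phase and a
#' dark recovery phase, with saturating pulses applied at a fixed cadence for
#' determination of Fm'.  The defaults reproduce the protocol used throughout
#' the package: 10 min far-red pre-illumination, 5 min actinic light at
#' 500 umol photons m-2 s-1, 5 min darkness, saturating pulses every minute
#' (5 light pulses followed by 5 dark pulses).
#'
#' @param fr_preillumination_s Far-red pre-illumination duration in seconds.
#' @param light_phase_s Actinic light phase duration in seconds.
#' @param dark_phase_s Dark recovery phase duration in seconds.
#' @param pulse_interval_s Interval between saturating pulses in seconds; must
#'   divide both phase durations.
#' @param actinic_intensity Actinic light intensity in umol photons m-2 s-1.
#' @param fr_in_dark Logical; is far-red light switched on during the dark
#'   recovery phase?
#'
#' @return An object of class `protocol_spec` with derived fields
#'   `n_light_pulses` and `n_dark_pulses`.
#' @examples
#' p <- protocol_spec()
#' p$n_light_pulses # 5
#' @export
protocol_spec <- function(fr_preillumination_s = 600,
                          light_phase_s = 300,
                          dark_phase_s = 300,
                          pulse_interval_s = 60,
                          actinic_intensity = 500,
                          fr_in_dark = FALSE) {
  durs <- c(fr_preillumination_s = fr_preillumination_s,
            light_phase_s = light_phase_s,
            dark_phase_s = dark_phase_s,
            pulse_interval_s = pulse_interval_s)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    abort_value("All protocol durations must be finite and > 0.")
  }
  if (light_phase_s %% pulse_interval_s != 0 || dark_phase_s %% pulse_interval_s != 0) {
    abort_value("pulse_interval_s must divide both light_phase_s and dark_phase_s.")
  }
  structure(
    list(
      fr_preillumination_s = fr_preillumination_s,
      light_phase_s = light_phase_s,
      dark_phase_s = dark_phase_s,
      pulse_interval_s = pulse_interval_s,
      actinic_intensity = actinic_intensity,
      fr_in_dark = isTRUE(fr_in_dark),
      n_light_pulses = light_phase_s %/% pulse_interval_s,
      n_dark_pulses = dark_phase_s %/% pulse_interval_s
    ),
    class = "protocol_spec"
  )
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("<protocol_spec>\n")
  cat(sprintf("  far-red pre-illumination: %d s\n", x$fr_preillumination_s))
  cat(sprintf("  light phase: %d s (%d pulses), actinic %g umol m-2 s-1\n",
              x$light_phase_s, x$n_light_pulses, x$actinic_intensity))
  cat(sprintf("  dark phase:  %d s (%d pulses), far-red %s\n",
              x$dark_phase_s, x$n_dark_pulses, if (x$fr_in_dark) "on" else "off"))
  invisible(x)
}

#' Saturating-pulse times for a protocol
#'
#' Pulse `k = 1..n_light` fires at `k * pulse_interval_s` after actinic light
#' onset; dark pulses continue at the same cadence through the dark phase.
#' The dark-adapted reference measurement (F0, Fm) is pulse 0 at time 0.
#'
#' @param protocol A [protocol_spec()].
#' @return Numeric vector of pulse times in seconds (length
#'   `n_light_pulses + n_dark_pulses`).
#' @export
pulse_times <- function(protocol) {
  n <- protocol$n_light_pulses + protocol$n_dark_pulses
  seq_len(n) * protocol$pulse_interval_s
}

# ---- well addresses ---------------------------------------------------------

plate_rows <- LETTERS[1:8]
plate_cols <- 1:12

#' 96-well plate address helpers
#'
#' Wells are addressed `"A1"`..`"H12"`.  In a gradient run the column index
#' determines the nominal temperature (the thermocycler imposes a per-column
#' gradient) and the rows within a column are biological replicates.
#'
#' @param well Character vector of well addresses.
#' @return `validate_well()` returns its input invisibly after checking;
#'   `well_row()`/`well_col()` return the row letter / column integer;
#'   `all_wells()` returns all 96 addresses in row-major order.
#' @examples
#' well_col("B7") # 7
#' @export
validate_well <- function(well) {
  ok <- grepl("^[A-H](1[0-2]|[1-9])$", well)
  if (!all(ok)) {
    abort_value(sprintf("Invalid well address(es): %s",
                        paste(well[!ok], collapse = ", ")))
  }
  invisible(well)
}

#' @rdname validate_well
#' @export
well_row <- function(well) {
  validate_well(well)
  substr(well, 1, 1)
}

#' @rdname validate_well
#' @export
well_col <- function(well) {
  validate_well(well)
  as.integer(substr(well, 2, nchar(well)))
}

#' @rdname validate_well
#' @export
all_wells <- function() {
  as.vector(t(outer(plate_rows, plate_cols, paste0)))
}
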