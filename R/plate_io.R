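# Reading/writing the CSV dialect for plate runs and derived tables.
#
# Numbers are written with 17 significant digits and re-parsed with base R's
# (correctly rounded) strtod, so writer and reader are exact mutual inverses.

read_csv_exact <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  out <- lapply(tab, function(x) utils::type.convert(x, as.is = TRUE))
  if (!is.null(out$well)) out$well <- as.character(out$well)
  if (!is.null(out$gradient_id)) out$gradient_id <- as.character(out$gradient_id)
  if (!is.null(out$run_id)) out$run_id <- as.character(out$run_id)
  num_cols <- intersect(c("time_s", "F", "Fm_prime", "temperature_C", "value"),
                        names(out))
  for (cc in num_cols) out[[cc]] <- as.numeric(out[[cc]])
  tibble::as_tibble(out)
}
#
# Trace table dialect: comma-separated, UTF-8, mandatory header, columns
# well, pulse_index, time_s, phase, F, Fm_prime.  The dark-adapted reference
# is pulse_index 0 with phase "ref", F = F0 and Fm_prime = Fm.  Run metadata
# travels in optional constant columns (gradient_id, fr_in_dark,
# growth_temperature, light_level) and per-well temperature in temperature_C.

trace_table_required <- c("well", "pulse_index", "time_s", "phase", "F", "Fm_prime")

#' Read a long-format saturating-pulse trace table
#'
#' @param path Path to a CSV file in the trace-table dialect (see
#'   [write_trace_table()] for the writer counterpart; the two round-trip to
#'   full precision).
#' @param protocol The [protocol_spec()] the traces were measured under; every
#'   well must carry exactly the pulse count the protocol implies.
#'
#' @return A [plate_run()].  Metadata columns present in the file (gradient
#'   id, far-red flag, acclimation, per-well temperature) are restored;
#'   unknown extra columns are kept in the run's `metadata` element.
#' @export
read_trace_table <- function(path, protocol = protocol_spec()) {
  if (!file.exists(path)) abort_io(sprintf("File not found: %s", path))
  tab <- read_csv_exact(path)
  miss <- setdiff(trace_table_required, names(tab))
  if (length(miss) > 0) {
    abort_format(sprintf("Trace table %s is missing required column(s): %s",
                         path, paste(miss, collapse = ", ")))
  }
  plate_run_from_table(tab, protocol)
}

plate_run_from_table <- function(tab, protocol) {
  n_exp <- protocol$n_light_pulses + protocol$n_dark_pulses
  if (any(!is.finite(tab$Fm_prime) | tab$Fm_prime <= 0)) {
    abort_value("Trace table contains non-positive Fm_prime values.")
  }
  extra <- setdiff(names(tab), c(trace_table_required, "temperature_C",
                                 "gradient_id", "fr_in_dark",
                                 "growth_temperature", "light_level"))
  wells <- unique(tab$well)
  traces <- vector("list", length(wells))
  names(traces) <- wells
  for (w in wells) {
    rows <- tab[tab$well == w, ]
    ref <- rows[rows$pulse_index == 0, ]
    pul <- rows[rows$pulse_index > 0, ]
    if (nrow(ref) != 1) {
      abort_incomplete_trace(sprintf("Well %s lacks the pulse_index 0 reference row.", w))
    }
    if (nrow(pul) != n_exp) {
      abort_incomplete_trace(sprintf("Well %s has %d pulses; protocol implies %d.",
                                     w, nrow(pul), n_exp))
    }
    traces[[w]] <- pulse_trace(
      well = w, f0 = ref$F, fm = ref$Fm_prime,
      pulses = tibble::tibble(index = as.integer(pul$pulse_index),
                              time_s = pul$time_s, f = pul$F,
                              fm_prime = pul$Fm_prime, phase = pul$phase))
  }
  well_temperature <- NULL
  if ("temperature_C" %in% names(tab)) {
    tt <- tab[!duplicated(tab$well), c("well", "temperature_C")]
    well_temperature <- stats::setNames(tt$temperature_C, tt$well)
  }
  acclimation <- list(growth_temperature = 26, light_level = "LL")
  if ("growth_temperature" %in% names(tab)) {
    acclimation$growth_temperature <- tab$growth_temperature[[1]]
  }
  if ("light_level" %in% names(tab)) acclimation$light_level <- tab$light_level[[1]]
  run <- plate_run(
    protocol = protocol, traces = traces,
    gradient_id = if ("gradient_id" %in% names(tab)) as.character(tab$gradient_id[[1]]) else "g1",
    well_temperature = well_temperature,
    fr_in_dark = if ("fr_in_dark" %in% names(tab)) isTRUE(tab$fr_in_dark[[1]]) else protocol$fr_in_dark,
    acclimation = acclimation)
  if (length(extra) > 0) run$metadata <- tab[, extra, drop = FALSE]
  run
}

#' Write a plate run as a long-format trace table
#'
#' Inverse of [read_trace_table()]: writing and re-reading reproduces every
#' fluorescence value to full precision.
#'
#' @param run A [plate_run()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(run, path) {
  stopifnot(inherits(run, "plate_run"))
  rows <- purrr::map(run$traces, function(tr) {
    ref <- tibble::tibble(well = tr$well, pulse_index = 0L, time_s = 0,
                          phase = "ref", F = tr$f0, Fm_prime = tr$fm)
    pul <- tibble::tibble(well = tr$well,
                          pulse_index = as.integer(tr$pulses$index),
                          time_s = tr$pulses$time_s, phase = tr$pulses$phase,
                          F = tr$pulses$f, Fm_prime = tr$pulses$fm_prime)
    dplyr::bind_rows(ref, pul)
  })
  tab <- dplyr::bind_rows(rows)
  tab$gradient_id <- run$gradient_id
  tab$fr_in_dark <- run$fr_in_dark
  tab$growth_temperature <- run$acclimation$growth_temperature
  tab$light_level <- run$acclimation$light_level
  if (!is.null(run$well_temperature)) {
    tab$temperature_C <- unname(run$well_temperature[tab$well])
  }
  write_csv_checked(tab, path)
}

write_csv_checked <- function(tab, path) {
  # format doubles to 17 significant digits so the reader restores every
  # value bit-identically (shortest-representation writers can be 1 ulp off)
  dbl_cols <- names(tab)[vapply(tab, is.double, logical(1))]
  tab <- dplyr::mutate(tab, dplyr::across(
    dplyr::all_of(dbl_cols),
    function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))))
  ok <- tryCatch({
    readr::write_csv(tab, path, progress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort_io(sprintf("Cannot write %s: %s", path, conditionMessage(ok)))
  invisible(path)
}

#' Assign nominal column temperatures to a plate run
#'
#' The thermocycler imposes one temperature per plate column; this maps a
#' column -> temperature gradient onto every well of the run.  Idempotent.
#' An optional per-well measured-temperature table overrides the nominal
#' column values.
#'
#' @param run A [plate_run()].
#' @param gradient Numeric vector of temperatures in deg C named by column
#'   number (`"1"`..`"12"`), covering every column present in the run.
#' @param measured Optional named numeric vector (names = wells) of measured
#'   per-well temperatures overriding the nominal column values.
#' @return The run with `well_temperature` set.
#' @export
assign_temperatures <- function(run, gradient, measured = NULL) {
  stopifnot(inherits(run, "plate_run"))
  if (is.null(names(gradient))) names(gradient) <- as.character(seq_along(gradient))
  wells <- names(run$traces)
  cols <- as.character(well_col(wells))
  miss <- setdiff(unique(cols), names(gradient))
  if (length(miss) > 0) {
    abort_config(sprintf("Gradient does not cover column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  temps <- stats::setNames(unname(gradient[cols]), wells)
  if (!is.null(measured)) {
    ov <- intersect(names(measured), wells)
    temps[ov] <- measured[ov]
  }
  check_well_temperatures(temps, wells)
  run$well_temperature <- temps
  run
}

# ---- thermal responses ------------------------------------------------------

#' Thermal response of one component
#'
#' A tidy set of (temperature, value) points for a single deconvoluted
#' component, pooled across gradient runs with provenance.  Overlapping
#' temperatures from different runs are kept as distinct replicate points.
#'
#' @param points Data frame with columns `temperature`, `value`, `run_id`,
#'   `well`.
#' @param component_name Label of the component the values belong to.
#' @return A tibble of class `thermal_response`, sorted by
#'   (temperature, run_id, well), with attribute `component_name`.
#' @export
thermal_response <- function(points, component_name) {
  points <- tibble::as_tibble(points)
  req <- c("temperature", "value", "run_id", "well")
  miss <- setdiff(req, names(points))
  if (length(miss) > 0) {
    abort_format(sprintf("Thermal response needs column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  if (nrow(points) == 0 || anyNA(points[req])) {
    abort_value("Thermal response points must be non-empty with no missing values.")
  }
  if (length(unique(points$temperature)) < 2) {
    abort_value("A thermal response needs >= 2 distinct temperatures.")
  }
  points <- dplyr::arrange(points[req], .data$temperature, .data$run_id, .data$well)
  structure(points, class = c("thermal_response", class(tibble::tibble()))) |>
    (\(x) { attr(x, "component_name") <- component_name; x })()
}

#' Replicate counts per temperature of a thermal response
#' @param response A [thermal_response()].
#' @return Tibble with columns `temperature`, `n`.
#' @export
replicate_counts <- function(response) {
  dplyr::count(tibble::as_tibble(response), .data$temperature, name = "n")
}

#' Merge overlapping gradient runs into one thermal response
#'
#' Concatenates per-well component values from several gradient runs onto a
#' single ascending temperature axis.  Points at overlapping temperatures are
#' retained as distinct replicates (never averaged away) and carry their
#' (run_id, well) provenance.  The result is invariant under permutation of
#' the input run list.
#'
#' @param runs List of [plate_run()]s sharing acclimation metadata and
#'   far-red flag, each with temperatures assigned.
#' @param component_values List (parallel to `runs`) of data frames with
#'   columns `well` and `value`.
#' @param component_name Label stored on the result.
#' @return A [thermal_response()].
#' @export
merge_gradient_runs <- function(runs, component_values, component_name = "component") {
  if (length(runs) < 1) abort_value("Need at least one run to merge.")
  if (length(component_values) != length(runs)) {
    abort_value("component_values must be parallel to runs.")
  }
  ref <- runs[[1]]
  for (run in runs[-1]) {
    same <- identical(run$acclimation, ref$acclimation) &&
      identical(run$fr_in_dark, ref$fr_in_dark)
    if (!same) {
      abort_merge("Runs with conflicting acclimation metadata or far-red flag cannot be merged.")
    }
  }
  pts <- purrr::map2(runs, component_values, function(run, vals) {
    if (is.null(run$well_temperature)) {
      abort_value(sprintf("Run %s has no temperatures assigned.", run$gradient_id))
    }
    vals <- tibble::as_tibble(vals)
    tibble::tibble(temperature = unname(run$well_temperature[vals$well]),
                   value = vals$value, run_id = run$gradient_id, well = vals$well)
  })
  thermal_response(dplyr::bind_rows(pts), component_name)
}

#' @export
print.thermal_response <- function(x, ...) {
  cat(sprintf("<thermal_response> %s: %d points, %d distinct temperatures (%.1f-%.1f C)\n",
              attr(x, "component_name"), nrow(x),
              length(unique(x$temperature)), min(x$temperature), max(x$temperature)))
  NextMethod()
}

# ---- component tables -------------------------------------------------------

#' Write per-well component values as a tidy table
#'
#' One row per well per component with temperature, provenance and
#' acclimation metadata; the counterpart [read_component_table()] restores
#' values to full precision.
#'
#' @param results Data frame with columns `well`, `temperature_C`,
#'   `component`, `value`, `run_id`, `growth_temperature`, `light_level`,
#'   `fr_in_dark`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_component_table <- function(results, path) {
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0) abort_value("Refusing to write an empty component table.")
  req <- c("well", "temperature_C", "component", "value", "run_id")
  miss <- setdiff(req, names(results))
  if (length(miss) > 0) {
    abort_format(sprintf("Component table needs column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  write_csv_checked(results, path)
}

#' @rdname write_component_table
#' @export
read_component_table <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("File not found: %s", path))
  read_csv_exact(path)
}
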