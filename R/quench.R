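# Fluorescence-derived quantities: Stern-Volmer NPQ, the NPQ component
# deconvolution with dynamic dark-phase Fm' selection, PSII yields and the
# Kramer energy partition.
#
# Notation: Fm is each well's own dark-adapted maximum fluorescence (after
# far-red pre-illumination), Fm'_k the maximum fluorescence at saturating
# pulse k, F the steady-state fluorescence just before a pulse.  Under the
# default protocol pulse 5 is the last light pulse and pulses 6-10 are taken
# in darkness; maxFm'(dark) and minFm'(dark) denote the extreme Fm' values
# over the dark pulses, ties broken by the earliest pulse.

#' Stern-Volmer non-photochemical quenching
#'
#' `NPQ = (Fm - Fm') / Fm'`.  Negative values (Fm' > Fm) are permitted — they
#' occur in real measurements, e.g. after the dark-transition NPQ spike — and
#' raise a warning rather than being clamped.
#'
#' @param fm Dark-adapted maximum fluorescence (a.u., > 0). Recycled.
#' @param fm_prime Light/dark-adapted maximum fluorescence during a
#'   saturating pulse (a.u., > 0).
#' @param warn Warn when any resulting NPQ is negative (default `TRUE`).
#' @return Dimensionless NPQ, same length as `fm_prime`.
#' @examples
#' npq(1, 0.5) # 1
#' @export
npq <- function(fm, fm_prime, warn = TRUE) {
  if (any(!is.finite(fm_prime)) || any(fm_prime <= 0)) {
    bad <- which(!is.finite(fm_prime) | fm_prime <= 0)
    abort_value(sprintf("Fm' must be > 0 (offending position(s): %s).",
                        paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(fm)) || any(fm <= 0)) abort_value("Fm must be > 0.")
  out <- (fm - fm_prime) / fm_prime
  if (warn && any(out < 0)) {
    qm_warn(sprintf("%d NPQ value(s) are negative (Fm' > Fm); not clamped.",
                    sum(out < 0)), "qm_negative_npq_warning")
  }
  out
}

#' NPQ at every saturating pulse of a trace
#'
#' @param trace A [pulse_trace()].
#' @inheritParams npq
#' @return Numeric vector: `npq(Fm, Fm'_k)` for k = 1..n pulses.
#' @export
npq_timeseries <- function(trace, warn = TRUE) {
  stopifnot(inherits(trace, "pulse_trace"))
  npq(trace$fm, trace$pulses$fm_prime, warn = warn)
}

# Dark-phase Fm' extrema with earliest-pulse tie-breaking.
dark_fm_prime_extrema <- function(trace) {
  dark <- trace$pulses[trace$pulses$phase == "dark", ]
  if (nrow(dark) == 0) {
    abort_incomplete_trace(sprintf("Well %s has no dark pulses.", trace$well))
  }
  i_max <- which.max(dark$fm_prime) # which.max/min take the first of ties
  i_min <- which.min(dark$fm_prime)
  list(max = dark$fm_prime[i_max], min = dark$fm_prime[i_min],
       index_max = dark$index[i_max], index_min = dark$index[i_min])
}

#' qE-type (fast-relaxing) NPQ
#'
#' The difference between NPQ at the end of the light phase and the minimum
#' NPQ reached during dark relaxation, using the dynamic dark-phase Fm'
#' maximum: `(Fm - Fm'_5)/Fm'_5 - (Fm - maxFm'_6-10)/maxFm'_6-10`.  May be
#' negative (high-light acclimated cultures show negative dips).
#'
#' @param trace A [pulse_trace()] with light and dark pulses.
#' @inheritParams npq
#' @return Dimensionless qE-type NPQ.
#' @export
qe_type_npq <- function(trace, warn = FALSE) {
  stopifnot(inherits(trace, "pulse_trace"))
  light <- trace$pulses[trace$pulses$phase == "light", ]
  if (nrow(light) == 0) abort_incomplete_trace(sprintf("Well %s has no light pulses.", trace$well))
  ex <- dark_fm_prime_extrema(trace)
  fm5 <- light$fm_prime[nrow(light)]
  npq(trace$fm, fm5, warn = warn) - npq(trace$fm, ex$max, warn = warn)
}

#' Slow-relaxing NPQ
#'
#' The minimum NPQ recorded during dark relaxation:
#' `(Fm - maxFm'_6-10)/maxFm'_6-10`, the quenching that has not relaxed
#' within the dark phase (zeaxanthin-dependent quenching, photoinhibition).
#'
#' @inheritParams qe_type_npq
#' @return Dimensionless slow-relaxing NPQ.
#' @export
slow_relaxing_npq <- function(trace, warn = FALSE) {
  stopifnot(inherits(trace, "pulse_trace"))
  ex <- dark_fm_prime_extrema(trace)
  npq(trace$fm, ex$max, warn = warn)
}

#' qT1-type (far-red-responsive) NPQ
#'
#' Difference of the minimum dark-phase NPQ between a measurement without and
#' with far-red light during dark recovery (state 1 transition):
#' `slow_relaxing_npq(-FR) - slow_relaxing_npq(+FR)`.  The two traces must
#' come from the same well address of paired runs.
#'
#' @param trace_no_fr Trace measured without far-red in the dark phase.
#' @param trace_fr Trace of the same well measured with far-red in the dark.
#' @inheritParams npq
#' @return Dimensionless qT1-type NPQ.
#' @export
qt1_type_npq <- function(trace_no_fr, trace_fr, warn = FALSE) {
  stopifnot(inherits(trace_no_fr, "pulse_trace"), inherits(trace_fr, "pulse_trace"))
  if (!identical(trace_no_fr$well, trace_fr$well)) {
    abort_pairing(sprintf("Traces from wells %s and %s cannot be paired for qT1.",
                          trace_no_fr$well, trace_fr$well))
  }
  slow_relaxing_npq(trace_no_fr, warn = warn) - slow_relaxing_npq(trace_fr, warn = warn)
}

#' qT2-type (dark-rise) NPQ
#'
#' Amplitude of the steady NPQ rise in darkness (state 1 to state 2
#' transition): the span between the minimum and maximum NPQ over the dark
#' pulses, `(Fm - minFm'_6-10)/minFm'_6-10 - (Fm - maxFm'_6-10)/maxFm'_6-10`.
#' Non-negative by construction.
#'
#' @inheritParams qe_type_npq
#' @return Dimensionless qT2-type NPQ (>= 0).
#' @export
qt2_type_npq <- function(trace, warn = FALSE) {
  stopifnot(inherits(trace, "pulse_trace"))
  ex <- dark_fm_prime_extrema(trace)
  npq(trace$fm, ex$min, warn = warn) - npq(trace$fm, ex$max, warn = warn)
}

#' Effective PSII quantum yield
#'
#' `Y(II) = (Fm' - F) / Fm'`.
#'
#' @param f Steady-state fluorescence (a.u., >= 0).
#' @param fm_prime Maximum fluorescence during the saturating pulse (> 0).
#' @return Dimensionless Y(II).
#' @export
quantum_yield_psii <- function(f, fm_prime) {
  if (any(!is.finite(fm_prime)) || any(fm_prime <= 0)) abort_value("Fm' must be > 0.")
  (fm_prime - f) / fm_prime
}

#' Maximum PSII quantum yield
#'
#' `Fv/Fm = (Fm - F0) / Fm` of the dark-adapted sample.
#'
#' @param f0 Minimal dark-adapted fluorescence (0 <= F0 <= Fm).
#' @param fm Maximum dark-adapted fluorescence (> 0).
#' @return Dimensionless Fv/Fm.
#' @export
fv_over_fm <- function(f0, fm) {
  if (any(!is.finite(fm)) || any(fm <= 0)) abort_value("Fm must be > 0.")
  if (any(f0 < 0) || any(f0 > fm)) abort_value("F0 must satisfy 0 <= F0 <= Fm.")
  (fm - f0) / fm
}

#' Kramer energy partition at a saturating pulse
#'
#' Partitions absorbed excitation energy into photochemistry `Y(II)`,
#' regulated losses `Y(NPQ)` and unregulated losses `Y(NO)`, summing to 1 by
#' construction.  `F0'` is not measured by the protocol; by default it is
#' estimated with the Oxborough-Baker relation
#' `F0' = F0 / (Fv/Fm + F0/Fm')`, from which
#' `qL = ((Fm' - F)/(Fm' - F0')) * (F0'/F)` and
#' `Y(NO) = 1 / (NPQ + 1 + qL * (Fm/F0 - 1))`.  The simplified lake-model
#' forms `Y(NO) = F/Fm`, `Y(NPQ) = F/Fm' - F/Fm` are available as a switch.
#'
#' @param trace A [pulse_trace()].
#' @param pulse_index Pulse at which to evaluate the partition (default 5,
#'   the end of the light phase).
#' @param f0_prime_method `"oxborough-baker"` (default) or `"lake"`.
#' @return A tibble with columns `y2`, `y_npq`, `y_no`, `q_l`, `f0_prime`.
#' @examples
#' tr <- pulse_trace("A1", 0.2, 1, data.frame(
#'   index = 1:10, time_s = 60 * (1:10), f = 0.3, fm_prime = 0.5,
#'   phase = rep(c("light", "dark"), each = 5)))
#' kramer_yields(tr) # Y(II)/Y(NPQ)/Y(NO) = 0.4/0.3/0.3
#' @export
kramer_yields <- function(trace, pulse_index = 5,
                          f0_prime_method = c("oxborough-baker", "lake")) {
  stopifnot(inherits(trace, "pulse_trace"))
  f0_prime_method <- match.arg(f0_prime_method)
  n <- nrow(trace$pulses)
  if (length(pulse_index) != 1 || pulse_index < 1 || pulse_index > n) {
    abort_value(sprintf("pulse_index must be in 1..%d.", n))
  }
  f0 <- trace$f0
  fm <- trace$fm
  f <- trace$pulses$f[pulse_index]
  fmp <- trace$pulses$fm_prime[pulse_index]
  if (f0 <= 0) abort_degenerate("Kramer partition needs F0 > 0.")
  if (f <= 0) abort_degenerate("Kramer partition needs F > 0.")
  fvfm <- fv_over_fm(f0, fm)
  f0p <- f0 / (fvfm + f0 / fmp)
  if (abs(fmp - f0p) < .Machine$double.eps * 16) {
    abort_degenerate("Kramer partition degenerate: Fm' equals the estimated F0'.")
  }
  q_l <- ((fmp - f) / (fmp - f0p)) * (f0p / f)
  y2 <- (fmp - f) / fmp
  if (f0_prime_method == "oxborough-baker") {
    npq_val <- (fm - fmp) / fmp
    y_no <- 1 / (npq_val + 1 + q_l * (fm / f0 - 1))
    y_npq <- 1 - y2 - y_no
  } else {
    y_no <- f / fm
    y_npq <- f / fmp - f / fm
  }
  tibble::tibble(y2 = y2, y_npq = y_npq, y_no = y_no, q_l = q_l, f0_prime = f0p)
}

#' Fraction of closed PSII reaction centres
#'
#' `1 - qL` at the given pulse, with qL from the Oxborough-Baker estimate
#' used by [kramer_yields()].
#'
#' @inheritParams kramer_yields
#' @return Dimensionless closed-centre fraction.
#' @export
closed_rc_fraction <- function(trace, pulse_index = 5) {
  1 - kramer_yields(trace, pulse_index)$q_l
}

#' Deconvolute one well's trace into NPQ components and yields
#'
#' Computes the full per-well summary from a single dynamic selection of the
#' dark-phase Fm' extrema: the NPQ time series, qE-type, slow-relaxing and
#' qT2-type NPQ, qT1-type NPQ when a paired far-red trace is supplied, Y(II)
#' at the last light pulse, Fv/Fm, the Kramer partition, and the dark-phase
#' Fm' extrema with the pulse indices at which they occur.
#'
#' @param trace A [pulse_trace()] (measured without far-red in the dark for
#'   qT1 purposes).
#' @param paired_fr_trace Optional [pulse_trace()] of the same well measured
#'   with far-red on in the dark; enables qT1.
#' @inheritParams npq
#' @return An object of class `npq_components` (a list).
#' @export
deconvolute_well <- function(trace, paired_fr_trace = NULL, warn = TRUE) {
  stopifnot(inherits(trace, "pulse_trace"))
  series <- npq_timeseries(trace, warn = warn)
  ex <- dark_fm_prime_extrema(trace)
  slow <- npq(trace$fm, ex$max, warn = FALSE)
  qe <- series[trace$n_light] - slow
  qt2 <- npq(trace$fm, ex$min, warn = FALSE) - slow
  qt1 <- if (!is.null(paired_fr_trace)) qt1_type_npq(trace, paired_fr_trace) else NA_real_
  i5 <- trace$n_light
  y2 <- quantum_yield_psii(trace$pulses$f[i5], trace$pulses$fm_prime[i5])
  kr <- kramer_yields(trace, pulse_index = i5)
  first_dark <- trace$n_light + 1
  structure(
    list(well = trace$well,
         npq_per_pulse = series,
         qe = qe, slow_relaxing = slow, qt2 = qt2, qt1 = qt1,
         y2 = y2, fv_fm = fv_over_fm(trace$f0, trace$fm),
         y_npq = kr$y_npq, y_no = kr$y_no, q_l = kr$q_l,
         closed_rc = 1 - kr$q_l,
         max_fm_prime_dark = ex$max, min_fm_prime_dark = ex$min,
         index_max_dark = ex$index_max, index_min_dark = ex$index_min,
         n_negative_npq = sum(series < 0),
         dark_spike = trace$pulses$fm_prime[first_dark] < trace$pulses$fm_prime[i5]),
    class = "npq_components")
}

#' @export
print.npq_components <- function(x, ...) {
  cat(sprintf("<npq_components> well %s\n", x$well))
  cat(sprintf("  qE = %.4f  slow = %.4f  qT2 = %.4f  qT1 = %s\n",
              x$qe, x$slow_relaxing, x$qt2,
              if (is.na(x$qt1)) "NA" else sprintf("%.4f", x$qt1)))
  cat(sprintf("  Y(II) = %.4f  Fv/Fm = %.4f  Y(NPQ) = %.4f  Y(NO) = %.4f\n",
              x$y2, x$fv_fm, x$y_npq, x$y_no))
  invisible(x)
}

#' Deconvolute every well of a plate run
#'
#' @param run A [plate_run()] (far-red off in dark for qT1 purposes).
#' @param paired_run Optional paired [plate_run()] with far-red on in dark;
#'   wells present in both runs get qT1 values.
#' @return A tibble with one row per well: the component values, dark-phase
#'   Fm' extrema diagnostics, the run's temperature (if assigned) and run id.
#' @export
deconvolute_run <- function(run, paired_run = NULL) {
  stopifnot(inherits(run, "plate_run"))
  if (!is.null(paired_run)) stopifnot(inherits(paired_run, "plate_run"))
  rows <- purrr::map(run$traces, function(tr) {
    pair <- if (!is.null(paired_run)) paired_run$traces[[tr$well]] else NULL
    cmp <- deconvolute_well(tr, paired_fr_trace = pair, warn = FALSE)
    tibble::tibble(
      well = cmp$well,
      qe = cmp$qe, slow_relaxing = cmp$slow_relaxing, qt2 = cmp$qt2, qt1 = cmp$qt1,
      y2 = cmp$y2, fv_fm = cmp$fv_fm, y_npq = cmp$y_npq, y_no = cmp$y_no,
      q_l = cmp$q_l, closed_rc = cmp$closed_rc,
      max_fm_prime_dark = cmp$max_fm_prime_dark,
      min_fm_prime_dark = cmp$min_fm_prime_dark,
      index_max_dark = cmp$index_max_dark, index_min_dark = cmp$index_min_dark,
      n_negative_npq = cmp$n_negative_npq, dark_spike = cmp$dark_spike)
  })
  out <- dplyr::bind_rows(rows)
  out$run_id <- run$gradient_id
  if (!is.null(run$well_temperature)) {
    out$temperature_C <- unname(run$well_temperature[out$well])
  }
  out
}
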