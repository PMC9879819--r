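# Synthetic PAM trace generator.
#
# Each component of photoprotection is given a thermal amplitude profile:
# a cubic dip for qE-type NPQ, bell-shaped biphasic Hill curves for the
# slow-relaxing and qT2-type pools and for the Y(II) optimum.  A kinetic
# model turns the profile values at a given temperature into a continuous
# NPQ(t) trajectory over the light and dark phases, which is then sampled at
# the protocol's saturating-pulse times and wrapped in multiplicative
# measurement noise.

# ---- profile building blocks ------------------------------------------------

# Cubic with an exact interior extremum: y(T) = dip + (T-Td)^2 * (b + c (T-Td)),
# with b, c solved from the prescribed values at the range edges.
qe_cubic_profile <- function(dip_temp, dip_value, value_low, value_high,
                             t_low = 10, t_high = 45) {
  dl <- t_low - dip_temp
  dh <- t_high - dip_temp
  A <- (value_low - dip_value) / dl^2
  B <- (value_high - dip_value) / dh^2
  cc <- (B - A) / (dh - dl)
  b <- A - cc * dl
  fun <- function(t) dip_value + (t - dip_temp)^2 * (b + cc * (t - dip_temp))
  list(fun = fun,
       params = c(dip_temp = dip_temp, dip_value = dip_value, b = b, c = cc))
}

# Bell-shaped biphasic Hill profile whose maximum sits exactly at peak_temp
# with value amplitude.  Given Ki, Hi, Ha, the activation midpoint Ka that
# places the maximum at peak_temp follows in closed form from d log(h)/dT = 0:
#   u/(1+u) = (Hi/Ha) * v/(1+v),  u = (Ka/Tp)^Ha, v = (Tp/Ki)^Hi.
bihill_bell_profile <- function(peak_temp, amplitude, baseline = 0,
                                ha = 8, hi = 35, ki_offset = 2.5) {
  ki <- peak_temp + ki_offset
  v <- (peak_temp / ki)^hi
  c0 <- (hi / ha) * v / (1 + v)
  if (c0 >= 1) {
    abort_config("Bell profile is infeasible: decrease hi, increase ha or ki_offset.")
  }
  u <- c0 / (1 - c0)
  ka <- peak_temp * u^(1 / ha)
  h <- function(t) 1 / ((1 + (ka / t)^ha) * (1 + (t / ki)^hi))
  hp <- h(peak_temp)
  fun <- function(t) baseline + (amplitude - baseline) * h(t) / hp
  list(fun = fun,
       params = c(peak_temp = peak_temp, amplitude = amplitude,
                  baseline = baseline, ka = ka, ha = ha, ki = ki, hi = hi))
}

#' Component thermal profiles for the trace simulator
#'
#' Defines, for one culture condition, how each deconvolution observable
#' depends on measurement temperature over 10-45 deg C:
#' * `qe` — a cubic with an exact interior dip (`dip_temp`, `dip_value`) and
#'   prescribed values at the range edges (`value_low` at 10 deg C,
#'   `value_high` at 45 deg C);
#' * `slow`, `qt2` — bell-shaped biphasic Hill profiles peaking at
#'   `peak_temp` with maximum `amplitude` (optional shape fields `ha`, `hi`,
#'   `ki_offset`);
#' * `qt2_fr_on` — the qT2 bell that applies when far-red light is on during
#'   dark recovery; the difference `qt2 - qt2_fr_on` is the far-red-responsive
#'   qT1 pool (defaults to `qt2`, i.e. qT1 = 0);
#' * `y2` — the Y(II) optimum bell (`opt_temp`, `amplitude`, `baseline`).
#'
#' The profiles state the *observable* component values a noise-free
#' measurement deconvolutes to; [simulate_trace()] calibrates the underlying
#' kinetic amplitudes so the protocol's pulse schedule reproduces them.
#'
#' @param qe List with `dip_temp`, `dip_value`, `value_low`, `value_high`.
#' @param slow List with `peak_temp`, `amplitude` (+ optional shape fields).
#' @param qt2 List with `peak_temp`, `amplitude` (+ optional shape fields).
#' @param y2 List with `opt_temp`, `amplitude`, optional `baseline` (default
#'   0.05) and shape fields.
#' @param qt2_fr_on Optional list like `qt2`; defaults to `qt2`.
#' @return An object of class `thermal_profile` exposing amplitude functions
#'   `qe_amp`, `slow_amp`, `qt2_amp`, `qt2_fr_on_amp`, `qt1_amp`, `y2_opt`.
#' @export
thermal_profile <- function(qe = list(dip_temp = 26, dip_value = 0.1,
                                      value_low = 0.35, value_high = 0.8),
                            slow = list(peak_temp = 40.5, amplitude = 1.0),
                            qt2 = list(peak_temp = 34.5, amplitude = 0.4),
                            y2 = list(opt_temp = 28.5, amplitude = 0.3),
                            qt2_fr_on = NULL) {
  qe_prof <- qe_cubic_profile(qe$dip_temp, qe$dip_value, qe$value_low, qe$value_high)
  slow_prof <- do.call(bihill_bell_profile, c(
    list(peak_temp = slow$peak_temp, amplitude = slow$amplitude),
    slow[intersect(names(slow), c("ha", "hi", "ki_offset"))],
    if (is.null(slow$ha)) list(ha = 8) else list()))
  qt2_shape <- function(spec) {
    do.call(bihill_bell_profile, c(
      list(peak_temp = spec$peak_temp, amplitude = spec$amplitude),
      spec[intersect(names(spec), c("ha", "hi", "ki_offset"))],
      if (is.null(spec$ha)) list(ha = 25) else list(),
      if (is.null(spec$hi)) list(hi = 40) else list()))
  }
  qt2_prof <- qt2_shape(qt2)
  qt2_on_prof <- if (is.null(qt2_fr_on)) qt2_prof else qt2_shape(qt2_fr_on)
  y2_prof <- do.call(bihill_bell_profile, c(
    list(peak_temp = y2$opt_temp, amplitude = y2$amplitude,
         baseline = y2$baseline %||% 0.05),
    y2[intersect(names(y2), c("ha", "hi", "ki_offset"))],
    if (is.null(y2$ha)) list(ha = 7) else list(),
    if (is.null(y2$hi)) list(hi = 25) else list(),
    if (is.null(y2$ki_offset)) list(ki_offset = 4) else list()))

  obj <- structure(
    list(qe_amp = qe_prof$fun,
         slow_amp = slow_prof$fun,
         qt2_amp = qt2_prof$fun,
         qt2_fr_on_amp = qt2_on_prof$fun,
         qt1_amp = function(t) qt2_prof$fun(t) - qt2_on_prof$fun(t),
         y2_opt = y2_prof$fun,
         params = list(qe = qe_prof$params, slow = slow_prof$params,
                       qt2 = qt2_prof$params, qt2_fr_on = qt2_on_prof$params,
                       y2 = y2_prof$params)),
    class = "thermal_profile")
  grid <- seq(10, 45, by = 0.5)
  checks <- c(obj$qe_amp(grid), obj$slow_amp(grid), obj$qt2_amp(grid),
              obj$qt2_fr_on_amp(grid), obj$y2_opt(grid))
  if (any(!is.finite(checks))) abort_value("Profile functions must be finite on 10-45 C.")
  if (any(obj$slow_amp(grid) < -1e-9) || any(obj$qt2_amp(grid) < -1e-9)) {
    abort_value("slow and qT2 amplitude profiles must be >= 0.")
  }
  y2v <- obj$y2_opt(grid)
  if (any(y2v < -1e-9) || any(y2v > 1 + 1e-9)) {
    abort_value("Y(II) profile must lie in [0, 1].")
  }
  obj
}

#' @export
print.thermal_profile <- function(x, ...) {
  p <- x$params
  cat("<thermal_profile>\n")
  cat(sprintf("  qE dip:   %.1f C, value %.3f\n", p$qe[["dip_temp"]], p$qe[["dip_value"]]))
  cat(sprintf("  slow:     peak %.1f C, amplitude %.3f\n",
              p$slow[["peak_temp"]], p$slow[["amplitude"]]))
  cat(sprintf("  qT2 -FR:  peak %.1f C, amplitude %.3f\n",
              p$qt2[["peak_temp"]], p$qt2[["amplitude"]]))
  cat(sprintf("  qT2 +FR:  peak %.1f C, amplitude %.3f\n",
              p$qt2_fr_on[["peak_temp"]], p$qt2_fr_on[["amplitude"]]))
  cat(sprintf("  Y(II):    optimum %.1f C, maximum %.3f\n",
              p$y2[["peak_temp"]], p$y2[["amplitude"]]))
  invisible(x)
}

#' Kinetic configuration of the trace simulator
#'
#' Time constants and noise model of the simulated fluorescence kinetics.
#' `tau_qe_induction`/`tau_qe_relaxation` govern qE build-up in light and
#' decay in darkness; the dark qT2 rise starts after `qt2_lag` seconds of
#' darkness with time constant `tau_qt2`; `dark_spike_amplitude` is the
#' transient NPQ excess at the first dark pulse (the light-to-dark "positive
#' spike").  Noise is multiplicative Gaussian with coefficient of variation
#' `noise_cv`, applied independently to every fluorescence reading.
#'
#' @param tau_qe_induction qE induction time constant in light (s).
#' @param tau_qe_relaxation qE relaxation time constant in darkness (s);
#'   should be well below `qt2_lag` (time-scale separation) — a warning is
#'   raised otherwise.
#' @param qt2_lag Lag before the dark qT2 rise starts (s).
#' @param tau_qt2 Time constant of the dark qT2 rise (s).
#' @param dark_spike_amplitude NPQ units added at the first dark pulse.
#' @param fm_base Dark-adapted Fm level (a.u.).
#' @param f0_over_fm F0 as a fraction of Fm (sets Fv/Fm = 1 - f0_over_fm).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Optional default seed used by [simulate_plate_run()].
#' @return An object of class `kinetic_config`.
#' @export
kinetic_config <- function(tau_qe_induction = 60, tau_qe_relaxation = 45,
                           qt2_lag = 120, tau_qt2 = 90,
                           dark_spike_amplitude = 0.05,
                           fm_base = 1.0, f0_over_fm = 0.2,
                           noise_cv = 0.02, seed = NULL) {
  taus <- c(tau_qe_induction, tau_qe_relaxation, qt2_lag, tau_qt2)
  if (any(!is.finite(taus)) || any(taus <= 0)) {
    abort_value("All kinetic time constants must be finite and > 0.")
  }
  if (fm_base <= 0 || f0_over_fm <= 0 || f0_over_fm >= 1) {
    abort_value("Need fm_base > 0 and 0 < f0_over_fm < 1.")
  }
  if (noise_cv < 0) abort_value("noise_cv must be >= 0.")
  if (tau_qe_relaxation > qt2_lag / 2) {
    qm_warn(paste0(
      "tau_qe_relaxation is not well separated from qt2_lag; ",
      "component recovery from simulated traces degrades without ",
      "time-scale separation."), "qm_timescale_warning")
  }
  structure(
    list(tau_qe_induction = tau_qe_induction,
         tau_qe_relaxation = tau_qe_relaxation,
         qt2_lag = qt2_lag, tau_qt2 = tau_qt2,
         dark_spike_amplitude = dark_spike_amplitude,
         fm_base = fm_base, f0_over_fm = f0_over_fm,
         noise_cv = noise_cv, seed = seed),
    class = "kinetic_config")
}

# ---- trajectory and calibration ---------------------------------------------

#' Continuous NPQ trajectory at one temperature
#'
#' Builds the simulator's NPQ(t) model: during the light phase
#' `NPQ(t) = (qe + slow) * (1 - exp(-t / tau_qe_induction))`; during the dark
#' phase (`t_d = t - light_phase_s`)
#' `NPQ = slow + qe * exp(-t_d / tau_qe_relaxation) + spike(t_d) +
#'  qt2_eff * max(0, 1 - exp(-(t_d - qt2_lag) / tau_qt2))`,
#' where `qt2_eff = qt2 - qt1` when far-red is on in the dark (the far-red
#' pool does not build up) and `qt2` otherwise, and `spike` adds
#' `dark_spike_amplitude` during the first pulse interval of darkness.
#'
#' @param profile A [thermal_profile()].
#' @param kinetics A [kinetic_config()].
#' @param temperature Measurement temperature in deg C (10-45).
#' @param fr_in_dark Far-red on during the dark phase?
#' @param protocol A [protocol_spec()] (sets the phase durations and the
#'   spike window).
#' @param amplitudes Optional list `(qe, slow, qt2)` overriding the profile
#'   values at `temperature` (used internally for calibrated amplitudes).
#' @return A vectorized function of time (s since actinic light onset)
#'   returning dimensionless NPQ.
#' @examples
#' traj <- npq_trajectory(thermal_profile(), kinetic_config(),
#'                        temperature = 26,
#'                        amplitudes = list(qe = 0.5, slow = 0.2, qt2 = 0))
#' traj(300) # 0.7 * (1 - exp(-5)) = 0.6953
#' @export
npq_trajectory <- function(profile, kinetics, temperature, fr_in_dark = FALSE,
                           protocol = protocol_spec(), amplitudes = NULL) {
  if (!is.finite(temperature) || temperature < 10 || temperature > 45) {
    abort_value("temperature must lie within 10-45 C.")
  }
  if (is.null(amplitudes)) {
    amplitudes <- list(
      qe = profile$qe_amp(temperature),
      slow = profile$slow_amp(temperature),
      qt2 = if (fr_in_dark) profile$qt2_fr_on_amp(temperature)
            else profile$qt2_amp(temperature))
  }
  qe <- amplitudes$qe
  slow <- amplitudes$slow
  qt2 <- amplitudes$qt2
  L <- protocol$light_phase_s
  spike_window <- protocol$pulse_interval_s
  k <- kinetics
  function(t) {
    out <- numeric(length(t))
    light <- t <= L
    out[light] <- (qe + slow) * (1 - exp(-t[light] / k$tau_qe_induction))
    td <- t[!light] - L
    spike <- k$dark_spike_amplitude * (td > 0 & td <= spike_window)
    rise <- pmax(0, 1 - exp(-(td - k$qt2_lag) / k$tau_qt2))
    out[!light] <- slow + qe * exp(-td / k$tau_qe_relaxation) + spike + qt2 * rise
    out
  }
}

# Underlying kinetic amplitudes that make the pulse-sampled deconvolution
# reproduce the profile's observable targets exactly at zero noise.  The
# trajectory attenuates amplitudes (finite induction: 1 - exp(-L/tau);
# truncated dark rise: 1 - exp(-(D - lag)/tau); residual qE at the dark
# minimum), so the targets are inverted by damped fixed-point iteration.
calibrate_amplitudes <- function(profile, kinetics, temperature,
                                 fr_in_dark = FALSE, protocol = protocol_spec()) {
  q_t <- profile$qe_amp(temperature)
  s_t <- profile$slow_amp(temperature)
  t2_t <- if (fr_in_dark) profile$qt2_fr_on_amp(temperature)
          else profile$qt2_amp(temperature)
  t2_t <- max(t2_t, 0)
  u <- list(qe = q_t, slow = max(s_t, 0), qt2 = t2_t)
  tp <- pulse_times(protocol)
  n_light <- protocol$n_light_pulses
  t5 <- tp[n_light]
  t_dark <- tp[(n_light + 1):length(tp)]
  for (iter in seq_len(50)) {
    traj <- npq_trajectory(profile, kinetics, temperature, fr_in_dark,
                           protocol, amplitudes = u)
    d <- traj(t_dark)
    meas_s <- min(d)
    meas_q <- traj(t5) - meas_s
    meas_t2 <- d[length(d)] - meas_s
    r <- c(q_t - meas_q, s_t - meas_s, t2_t - meas_t2)
    new_slow <- max(u$slow + r[2], 0)
    new_qt2 <- max(u$qt2 + r[3], 0)
    active <- c(TRUE, new_slow > 0 || r[2] > 0, new_qt2 > 0 || r[3] > 0)
    u <- list(qe = u$qe + r[1], slow = new_slow, qt2 = new_qt2)
    if (max(abs(r[active])) < 1e-10) break
  }
  u
}

# ---- trace and plate simulation ---------------------------------------------

#' Simulate a single well's saturating-pulse trace
#'
#' Samples the NPQ trajectory at the protocol's pulse times and converts to
#' fluorescence: `Fm' = Fm / (1 + NPQ)`, `F = Fm' * (1 - Y(II))` during
#' light, F relaxing from its light-phase level towards F0 in darkness, and
#' `F0 = f0_over_fm * Fm`.  Multiplicative Gaussian noise with CV `noise_cv`
#' is applied independently to every reading (draw order: F0, Fm, then
#' (Fm', F) per pulse).  By default the underlying kinetic amplitudes are
#' calibrated so that the noise-free deconvolution reproduces the profile's
#' configured component values exactly (see the methods vignette);
#' `calibrate = FALSE` uses the profile values directly in the trajectory.
#'
#' @inheritParams npq_trajectory
#' @param well Well address for the returned trace.
#' @param rng_seed Optional integer seed for this trace's noise draws (the
#'   caller's RNG state is preserved); if `NULL`, draws come from the current
#'   RNG stream.
#' @param calibrate Calibrate underlying amplitudes to the observable targets
#'   (default `TRUE`).
#' @param clamp Clamp noisy Fm' at Fm (default `FALSE`: exceedances are kept
#'   and counted in the trace's `fmp_exceedances` attribute).
#' @param warn Warn when noisy Fm' exceeds Fm (default `TRUE`).
#' @return A [pulse_trace()] with attribute `fmp_exceedances`.
#' @export
simulate_trace <- function(profile, kinetics, temperature, fr_in_dark = FALSE,
                           well = "A1", protocol = protocol_spec(),
                           rng_seed = NULL, calibrate = TRUE, clamp = FALSE,
                           warn = TRUE, amplitudes = NULL) {
  stopifnot(inherits(profile, "thermal_profile"), inherits(kinetics, "kinetic_config"))
  if (is.null(amplitudes)) {
    amplitudes <- if (calibrate) {
      calibrate_amplitudes(profile, kinetics, temperature, fr_in_dark, protocol)
    } else NULL
  }
  traj <- npq_trajectory(profile, kinetics, temperature, fr_in_dark, protocol,
                         amplitudes = amplitudes)
  tp <- pulse_times(protocol)
  n_light <- protocol$n_light_pulses
  n_pulse <- length(tp)
  npq_clean <- traj(tp)
  if (any(npq_clean <= -1)) {
    abort_value("Simulated NPQ <= -1 would imply non-positive Fm'.")
  }
  fm <- kinetics$fm_base
  f0 <- kinetics$f0_over_fm * fm
  fmp <- fm / (1 + npq_clean)
  y2v <- profile$y2_opt(temperature)
  f <- numeric(n_pulse)
  f[seq_len(n_light)] <- fmp[seq_len(n_light)] * (1 - y2v)
  f5 <- f[n_light]
  td <- tp[(n_light + 1):n_pulse] - protocol$light_phase_s
  f[(n_light + 1):n_pulse] <- f0 + (f5 - f0) * exp(-td / kinetics$tau_qe_relaxation)

  cv <- kinetics$noise_cv
  if (cv > 0) {
    z <- if (!is.null(rng_seed)) {
      withr::with_seed(as.integer(rng_seed), stats::rnorm(2 + 2 * n_pulse))
    } else {
      stats::rnorm(2 + 2 * n_pulse)
    }
    f0 <- f0 * (1 + cv * z[1])
    fm <- fm * (1 + cv * z[2])
    fmp <- fmp * (1 + cv * z[seq(3, by = 2, length.out = n_pulse)])
    f <- f * (1 + cv * z[seq(4, by = 2, length.out = n_pulse)])
  }
  exceed <- sum(fmp > fm)
  if (exceed > 0) {
    if (clamp) {
      fmp <- pmin(fmp, fm)
    } else if (warn) {
      qm_warn(sprintf("Well %s: %d noisy Fm' reading(s) exceed Fm (not clamped).",
                      well, exceed), "qm_fmp_exceedance_warning")
    }
  }
  tr <- pulse_trace(
    well = well, f0 = max(f0, 0), fm = fm,
    pulses = tibble::tibble(
      index = seq_len(n_pulse), time_s = tp,
      f = pmax(f, 0), fm_prime = fmp,
      phase = c(rep("light", n_light), rep("dark", n_pulse - n_light))))
  attr(tr, "fmp_exceedances") <- exceed
  tr
}

#' Deterministic per-well RNG substream seed
#'
#' Derives the noise seed for one well from the run seed and the well's row
#' and column through a fixed multiplicative-hash counter scheme,
#' `((seed * 48271) + 1009 * row + 101 * column) mod (2^31 - 1)`, so that
#' simulated plates are identical regardless of well iteration order.
#'
#' @param seed Integer run seed.
#' @param well Well address.
#' @return Integer seed below 2^31.
#' @export
well_substream_seed <- function(seed, well) {
  r <- match(well_row(well), LETTERS)
  cc <- well_col(well)
  s1 <- (as.double(seed) * 48271) %% 2147483647
  as.integer((s1 + 1009 * r + 101 * cc) %% 2147483647)
}

#' Simulate a full gradient plate run
#'
#' One trace per used well; the column index sets the temperature through
#' `gradient`, rows are biological replicates (default rows A-D, n = 4).
#' Each well's noise uses its own deterministic substream
#' ([well_substream_seed()]), so the result does not depend on generation
#' order.  Calibration of underlying amplitudes is shared per column.
#'
#' @param preset A `sim_preset` (see [preset_from_table1()]) or a
#'   [thermal_profile()].
#' @param gradient Numeric vector of column temperatures in deg C, named by
#'   column number (unnamed vectors are taken as columns 1..length).
#' @param kinetics A [kinetic_config()].
#' @param fr_in_dark Far-red on during dark recovery?
#' @param seed Integer seed for the run's noise (mandatory when
#'   `noise_cv > 0` unless `kinetics$seed` is set).
#' @param rows Replicate rows to fill (default `c("A","B","C","D")`).
#' @param gradient_id Run label.
#' @param protocol A [protocol_spec()].
#' @param calibrate Passed to [simulate_trace()].
#' @return A [plate_run()] with temperatures assigned and an
#'   `n_fmp_exceedances` element counting noisy Fm' > Fm readings.
#' @export
simulate_plate_run <- function(preset, gradient, kinetics = kinetic_config(),
                               fr_in_dark = FALSE, seed = NULL,
                               rows = LETTERS[1:4], gradient_id = "g1",
                               protocol = protocol_spec(), calibrate = TRUE) {
  if (inherits(preset, "sim_preset")) {
    profile <- preset$profile
    acclimation <- preset$acclimation
  } else if (inherits(preset, "thermal_profile")) {
    profile <- preset
    acclimation <- list(growth_temperature = 26, light_level = "LL")
  } else {
    abort_config("preset must be a sim_preset or a thermal_profile.")
  }
  if (is.null(names(gradient))) names(gradient) <- as.character(seq_along(gradient))
  if (is.null(seed)) seed <- kinetics$seed
  if (kinetics$noise_cv > 0 && is.null(seed)) {
    abort_config("A seed is required to simulate with noise_cv > 0.")
  }
  seed <- seed %||% 0L

  traces <- list()
  exceed <- 0L
  for (col_name in names(gradient)) {
    temp <- gradient[[col_name]]
    amps <- if (calibrate) {
      calibrate_amplitudes(profile, kinetics, temp, fr_in_dark, protocol)
    } else NULL
    for (row in rows) {
      w <- paste0(row, col_name)
      tr <- simulate_trace(profile, kinetics, temp, fr_in_dark, well = w,
                           protocol = protocol,
                           rng_seed = well_substream_seed(seed, w),
                           calibrate = calibrate, warn = FALSE,
                           amplitudes = amps)
      exceed <- exceed + attr(tr, "fmp_exceedances")
      traces[[w]] <- tr
    }
  }
  run <- plate_run(protocol = protocol, traces = traces,
                   gradient_id = gradient_id, fr_in_dark = fr_in_dark,
                   acclimation = acclimation)
  run <- assign_temperatures(run, gradient)
  run$n_fmp_exceedances <- exceed
  run
}

# ---- presets and gradients --------------------------------------------------

#' Shipped simulation presets
#'
#' Six presets named `<light>-<temperature>C` (`LL-19C`, `LL-26C`, `LL-29C`,
#' `HL-19C`, `HL-26C`, `HL-29C`) whose qE dip, qT2 peak (with and without
#' far-red in the dark), slow-relaxing peak and Y(II) optimum positions and
#' amplitudes follow the reference fitted-values table for the corresponding
#' acclimation condition (low/high growth light at 19, 26 or 29 deg C).  The
#' parameters live in the packaged, human-readable file
#' `inst/extdata/presets.yml` and can be copied and edited by users.
#'
#' @param name Preset name.
#' @return `preset_from_table1()`: an object of class `sim_preset` (elements
#'   `name`, `profile`, `acclimation`); `list_presets()`: the available
#'   names.
#' @export
preset_from_table1 <- function(name) {
  cfg <- yaml::read_yaml(system.file("extdata", "presets.yml",
                                     package = "quenchmap", mustWork = TRUE))
  if (!name %in% names(cfg$presets)) {
    abort_config(sprintf("Unknown preset '%s'; available: %s",
                         name, paste(names(cfg$presets), collapse = ", ")))
  }
  p <- cfg$presets[[name]]
  profile <- thermal_profile(
    qe = p$qe,
    slow = p$slow,
    qt2 = p$qt2,
    y2 = list(opt_temp = p$y2$opt_temp, amplitude = p$y2$amplitude,
              baseline = p$y2$baseline %||% 0.05,
              hi = p$y2$hi %||% 25),
    qt2_fr_on = p$qt2_fr_on)
  structure(list(name = name, profile = profile,
                 acclimation = list(
                   growth_temperature = p$acclimation$growth_temperature,
                   light_level = p$acclimation$light_level)),
            class = "sim_preset")
}

#' @rdname preset_from_table1
#' @export
list_presets <- function() {
  cfg <- yaml::read_yaml(system.file("extdata", "presets.yml",
                                     package = "quenchmap", mustWork = TRUE))
  names(cfg$presets)
}

#' @export
print.sim_preset <- function(x, ...) {
  cat(sprintf("<sim_preset> %s (%s, %g C acclimation)\n",
              x$name, x$acclimation$light_level, x$acclimation$growth_temperature))
  print(x$profile)
  invisible(x)
}

#' Default overlapping temperature gradients
#'
#' Four 12-column linear gradients in 1 deg C steps — 10-21, 18-29, 26-37 and
#' 34-45 deg C — overlapping by four columns and jointly spanning the full
#' 10-45 deg C range.
#'
#' @return Named list of four gradients (numeric vectors named by column).
#' @export
default_gradients <- function() {
  g <- function(from) stats::setNames(seq(from, from + 11), as.character(1:12))
  list(g1 = g(10), g2 = g(18), g3 = g(26), g4 = g(34))
}
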