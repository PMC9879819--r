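test_that("NPQ trajectory follows the phase model", {
  prof <- thermal_profile()
  kin <- kinetic_config()
  zero <- npq_trajectory(prof, kin, 26,
                         amplitudes = list(qe = 0, slow = 0, qt2 = 0))
  expect_equal(zero(c(0, 100, 300, 400, 600)), rep(0, 5))

  traj <- npq_trajectory(prof, kin, 26,
                         amplitudes = list(qe = 0.5, slow = 0.2, qt2 = 0))
  expect_equal(traj(300), 0.7 * (1 - exp(-5)), tolerance = 1e-12)
  # dark minimum approaches the slow pool once qE has relaxed; the residual
  # qE at the end of the dark phase is 0.5 * exp(-300/45) = 0.00064
  dark_grid <- seq(301, 600, by = 1)
  expect_equal(min(traj(dark_grid)), 0.2, tolerance = 5e-3)

  # the dark rise only starts after the lag
  t2 <- npq_trajectory(prof, kin, 26,
                       amplitudes = list(qe = 0, slow = 0, qt2 = 0.4))
  expect_equal(t2(300 + 120), 0)
  expect_equal(t2(600), 0.4 * (1 - exp(-(300 - 120) / 90)), tolerance = 1e-12)

  expect_error(npq_trajectory(prof, kin, 50), class = "qm_value_error")
})

test_that("kinetic config validates and warns on poor time-scale separation", {
  expect_error(kinetic_config(tau_qt2 = -1), class = "qm_value_error")
  expect_warning(kinetic_config(tau_qe_relaxation = 100),
                 class = "qm_timescale_warning")
})

test_that("uncalibrated component recovery stays within the analytic bounds", {
  prof <- thermal_profile()
  kin <- kinetic_config(noise_cv = 0)
  tr <- simulate_trace(prof, kin, 26, calibrate = FALSE, warn = FALSE,
                       amplitudes = list(qe = 0.5, slow = 0.2, qt2 = 0))
  # residual induction shortfall (1 - e^-5) and dark relaxation tail e^(-240/45)
  expect_lt(abs(qe_type_npq(tr) - 0.5) / 0.5, 0.015)
  expect_lt(abs(slow_relaxing_npq(tr) - 0.2) / 0.2, 0.005)

  # qT2 recovery within 5% when qt2_lag + 2 tau_qt2 <= dark phase (the
  # kinetic-truncation bound; the dark-spike artefact is assessed separately)
  kin2 <- kinetic_config(qt2_lag = 90, tau_qt2 = 60, noise_cv = 0,
                         dark_spike_amplitude = 0)
  tr2 <- simulate_trace(prof, kin2, 35, calibrate = FALSE, warn = FALSE,
                        amplitudes = list(qe = 0, slow = 0.3, qt2 = 0.4))
  expect_lt(abs(qt2_type_npq(tr2) - 0.4) / 0.4, 0.05)
})

test_that("calibrated traces reproduce the configured observables exactly", {
  prof <- preset_from_table1("LL-26C")$profile
  kin <- kinetic_config(noise_cv = 0)
  for (T in c(25.9, 28.6, 34.6, 40.9)) {
    tr <- simulate_trace(prof, kin, T, warn = FALSE)
    expect_equal(qe_type_npq(tr), prof$qe_amp(T), tolerance = 1e-8)
    expect_equal(slow_relaxing_npq(tr), prof$slow_amp(T), tolerance = 1e-8)
    expect_equal(quantum_yield_psii(tr$pulses$f[5], tr$pulses$fm_prime[5]),
                 prof$y2_opt(T), tolerance = 1e-8)
  }
  # the dark rise matches the configured qT2 bell where it is active
  tr <- simulate_trace(prof, kin, 34.6, warn = FALSE)
  expect_equal(qt2_type_npq(tr), prof$qt2_amp(34.6), tolerance = 1e-8)
  # far-red on: the qT2 rise is reduced to the +FR bell
  tr_fr <- simulate_trace(prof, kin, 34.6, fr_in_dark = TRUE, warn = FALSE)
  expect_equal(qt2_type_npq(tr_fr), prof$qt2_fr_on_amp(34.6), tolerance = 1e-8)
  expect_lt(qt2_type_npq(tr_fr), qt2_type_npq(tr))
})

test_that("trace simulation honours noise, seeds and clamping contracts", {
  prof <- thermal_profile()
  kin0 <- kinetic_config(noise_cv = 0)
  # zero amplitudes, zero noise: Fm' = Fm and F follows the Y(II) profile
  flatprof <- thermal_profile(qe = list(dip_temp = 26, dip_value = 0,
                                        value_low = 0, value_high = 0),
                              slow = list(peak_temp = 40, amplitude = 0),
                              qt2 = list(peak_temp = 35, amplitude = 0),
                              y2 = list(opt_temp = 28, amplitude = 0.3))
  kinq <- kinetic_config(noise_cv = 0, dark_spike_amplitude = 0)
  tr <- simulate_trace(flatprof, kinq, 28, warn = FALSE)
  expect_equal(tr$pulses$fm_prime, rep(1, 10))
  expect_equal(tr$pulses$f[1:5], rep(1 - flatprof$y2_opt(28), 5), tolerance = 1e-12)

  kin <- kinetic_config(noise_cv = 0.02)
  a <- simulate_trace(prof, kin, 30, rng_seed = 77, warn = FALSE)
  b <- simulate_trace(prof, kin, 30, rng_seed = 77, warn = FALSE)
  expect_identical(a$pulses, b$pulses)
  c2 <- simulate_trace(prof, kin, 30, rng_seed = 78, warn = FALSE)
  expect_false(identical(a$pulses$fm_prime, c2$pulses$fm_prime))

  # clamping keeps Fm' at or below Fm; default leaves exceedances and counts them
  noisy <- kinetic_config(noise_cv = 0.1)
  tr_cl <- simulate_trace(flatprof, noisy, 28, rng_seed = 5, clamp = TRUE, warn = FALSE)
  expect_true(all(tr_cl$pulses$fm_prime <= tr_cl$fm))
  tr_free <- simulate_trace(flatprof, noisy, 28, rng_seed = 5, warn = FALSE)
  expect_gte(attr(tr_free, "fmp_exceedances"), 1)
  expect_warning(simulate_trace(flatprof, noisy, 28, rng_seed = 5),
                 class = "qm_fmp_exceedance_warning")
})

test_that("simulated dark spikes reproduce Fm'6 < Fm'5 where qE is absent", {
  # the spike outweighs the qE relaxation drop only where qE ~ 0
  prof <- thermal_profile(qe = list(dip_temp = 26, dip_value = 0,
                                    value_low = 0, value_high = 0),
                          slow = list(peak_temp = 40, amplitude = 0.4),
                          qt2 = list(peak_temp = 35, amplitude = 0.3),
                          y2 = list(opt_temp = 28, amplitude = 0.3))
  kin <- kinetic_config(noise_cv = 0)
  tr <- simulate_trace(prof, kin, 35, warn = FALSE)
  expect_lt(tr$pulses$fm_prime[6], tr$pulses$fm_prime[5])
  expect_gte(slow_relaxing_npq(tr), 0)
  cmp <- deconvolute_well(tr, warn = FALSE)
  expect_true(cmp$dark_spike)
})

test_that("plate runs are deterministic and independent of iteration order", {
  grad <- c("1" = 20, "2" = 25, "3" = 30)
  preset <- preset_from_table1("LL-26C")
  kin <- kinetic_config(noise_cv = 0.02)
  r1 <- simulate_plate_run(preset, grad, kin, seed = 9)
  r2 <- simulate_plate_run(preset, grad, kin, seed = 9)
  for (w in names(r1$traces)) expect_identical(r1$traces[[w]]$pulses, r2$traces[[w]]$pulses)
  # reversed replicate rows: same per-well traces
  r3 <- simulate_plate_run(preset, grad, kin, seed = 9, rows = c("D", "C", "B", "A"))
  expect_identical(r3$traces[["B2"]]$pulses, r1$traces[["B2"]]$pulses)
  # different seed: same noiseless backbone, different noise
  r4 <- simulate_plate_run(preset, grad, kin, seed = 10)
  expect_false(identical(r4$traces[["A1"]]$pulses$fm_prime,
                         r1$traces[["A1"]]$pulses$fm_prime))
  r0a <- simulate_plate_run(preset, grad, kinetic_config(noise_cv = 0), seed = 9)
  r0b <- simulate_plate_run(preset, grad, kinetic_config(noise_cv = 0), seed = 10)
  expect_identical(r0a$traces[["A1"]]$pulses, r0b$traces[["A1"]]$pulses)
  # zero noise: replicate rows within a column are identical
  expect_identical(r0a$traces[["A1"]]$pulses, r0a$traces[["D1"]]$pulses)
  # noise requires a seed
  expect_error(simulate_plate_run(preset, grad, kin), class = "qm_config_error")
})

test_that("bootstrap uncertainty of the recovered peak is non-decreasing in noise", {
  bell <- function(t) 0.772 / ((1 + (37.5 / t)^8) * (1 + (t / 43.4)^35))
  uncert <- vapply(c(0, 0.02, 0.05), function(cv) {
    resp <- withr::with_seed(600 + round(1000 * cv),
                             make_response(bell, noise_cv = cv))
    bootstrap_extremum(resp, "bihill", "peak", n_boot = 500, seed = 12)$uncertainty
  }, numeric(1))
  expect_lt(uncert[1], 1e-9)
  expect_true(all(diff(uncert) >= -1e-9))
})

test_that("the six shipped presets carry the published dip/peak configuration", {
  expect_setequal(list_presets(),
                  c("LL-19C", "LL-26C", "LL-29C", "HL-19C", "HL-26C", "HL-29C"))
  ll26 <- preset_from_table1("LL-26C")
  expect_equal(unname(ll26$profile$params$qe[["dip_temp"]]), 25.9)
  expect_equal(unname(ll26$profile$params$qe[["dip_value"]]), 0.094)
  expect_equal(unname(ll26$profile$params$slow[["peak_temp"]]), 40.9)
  expect_equal(unname(ll26$profile$params$slow[["amplitude"]]), 0.772)
  expect_equal(unname(ll26$profile$params$qt2[["amplitude"]]), 0.355)
  expect_equal(unname(ll26$profile$params$qt2_fr_on[["amplitude"]]), 0.238)
  expect_equal(unname(ll26$profile$params$y2[["amplitude"]]), 0.26)
  expect_identical(ll26$acclimation$light_level, "LL")
  hl26 <- preset_from_table1("HL-26C")
  expect_equal(unname(hl26$profile$params$qe[["dip_value"]]), -0.019)
  expect_equal(unname(hl26$profile$params$slow[["peak_temp"]]), 40.5)
  # the bells peak exactly where configured, at the configured amplitude
  g <- seq(10, 45, 0.001)
  sl <- ll26$profile$slow_amp(g)
  expect_equal(g[which.max(sl)], 40.9, tolerance = 2e-3)
  expect_equal(max(sl), 0.772, tolerance = 1e-9)
  expect_error(preset_from_table1("XX-00C"), class = "qm_config_error")
})

test_that("profile invariants reject infeasible configurations", {
  expect_error(thermal_profile(y2 = list(opt_temp = 28, amplitude = 1.5)),
               class = "qm_value_error")
  expect_error(thermal_profile(slow = list(peak_temp = 40, amplitude = -1)),
               class = "qm_value_error")
})

test_that("well substream seeds are stable and well-distributed", {
  s1 <- well_substream_seed(1, "A1")
  expect_identical(s1, well_substream_seed(1, "A1"))
  seeds <- vapply(all_wells(), function(w) well_substream_seed(123, w), integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  expect_true(all(seeds >= 0 & seeds < 2^31))
})
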