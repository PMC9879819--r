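# Shared fixtures, built in code.

# A hand-specified trace: Fm' per pulse, constant F unless given.
make_trace <- function(fm_prime, fm = 1, f0 = 0.2, f = NULL, well = "A1",
                       n_light = 5) {
  n <- length(fm_prime)
  if (is.null(f)) f <- fm_prime * 0.6
  pulse_trace(well, f0, fm, data.frame(
    index = seq_len(n), time_s = 60 * seq_len(n), f = f, fm_prime = fm_prime,
    phase = c(rep("light", n_light), rep("dark", n - n_light))))
}

# A random valid trace drawn from the current RNG stream.
random_trace <- function(well = "A1") {
  fm <- stats::runif(1, 0.8, 1.5)
  f0 <- fm * stats::runif(1, 0.1, 0.3)
  fm_prime <- fm * stats::runif(10, 0.3, 1.1)
  f <- fm_prime * stats::runif(10, 0.05, 0.95)
  make_trace(fm_prime, fm = fm, f0 = f0, f = f, well = well)
}

# Thermal response sampled from a function of temperature, with replicates
# and optional multiplicative noise (drawn from the current RNG stream).
make_response <- function(fun, temps = seq(10, 45, by = 1), reps = 4,
                          noise_cv = 0, name = "test") {
  grid <- rep(temps, each = reps)
  vals <- fun(grid)
  if (noise_cv > 0) vals <- vals * (1 + noise_cv * stats::rnorm(length(vals)))
  thermal_response(
    data.frame(temperature = grid, value = vals, run_id = "g1",
               well = paste0(rep(LETTERS[seq_len(reps)], times = length(temps)),
                             rep(seq_along(temps), each = reps))),
    name)
}

# A tiny simulated plate run (few columns) for I/O tests.
small_sim_run <- function(seed = 7, cols = 4, noise_cv = 0.02,
                          fr_in_dark = FALSE, gradient_id = "g1") {
  gradient <- stats::setNames(seq(20, by = 2, length.out = cols),
                              as.character(seq_len(cols)))
  simulate_plate_run(
    preset_from_table1("LL-26C"), gradient,
    kinetics = kinetic_config(noise_cv = noise_cv),
    fr_in_dark = fr_in_dark, seed = seed, gradient_id = gradient_id)
}
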