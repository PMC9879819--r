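test_that("cubic fit recovers polynomial coefficients exactly", {
  const <- make_response(function(t) rep(2, length(t)))
  fc <- fit_cubic(const)
  expect_equal(unname(fc$coefficients), c(2, 0, 0, 0), tolerance = 1e-9)

  # y = (T - 26)^2 = 676 - 52 T + T^2 on the cubic basis
  para <- make_response(function(t) (t - 26)^2)
  fp <- fit_cubic(para)
  expect_equal(unname(fp$coefficients), c(676, -52, 1, 0), tolerance = 1e-6)

  few <- thermal_response(data.frame(temperature = rep(c(10, 20, 30), 2),
                                     value = 1:6, run_id = "g", well = "A1"), "x")
  expect_error(fit_cubic(few), class = "qm_insufficient_data_error")
})

test_that("biphasic Hill fit recovers its own parameters from noiseless data", {
  truth <- c(y0 = 0, pm = 1, ka = 30, ha = 10, ki = 40, hi = 10)
  fun <- function(t) truth[["y0"]] + truth[["pm"]] /
    ((1 + (truth[["ka"]] / t)^truth[["ha"]]) * (1 + (t / truth[["ki"]])^truth[["hi"]]))
  resp <- make_response(fun, temps = seq(10, 45, by = 0.5), reps = 1)
  fit <- fit_bihill(resp, "peak")
  expect_equal(unname(fit$parameters[c("pm", "ka", "ha", "ki", "hi")]),
               unname(truth[c("pm", "ka", "ha", "ki", "hi")]), tolerance = 1e-4)
  expect_lt(abs(fit$parameters[["y0"]]), 1e-6)

  # permutation invariance
  perm <- withr::with_seed(5, sample(nrow(resp)))
  resp_perm <- thermal_response(tibble::as_tibble(resp)[perm, ], "test")
  fit2 <- fit_bihill(resp_perm, "peak")
  expect_identical(fit$parameters, fit2$parameters)

  flat <- make_response(function(t) rep(1, length(t)))
  expect_error(fit_bihill(flat, "peak"), class = "qm_fit_failure_error")
})

test_that("insufficient distinct temperatures abort the biphasic Hill fit", {
  resp <- thermal_response(
    data.frame(temperature = rep(c(10, 20, 30, 35, 40), each = 2),
               value = rep(c(0.1, 0.5, 1, 0.8, 0.2), each = 2),
               run_id = "g", well = "A1"), "x")
  expect_error(fit_bihill(resp, "peak"), class = "qm_insufficient_data_error")
})

test_that("cubic extremum matches the closed-form derivative root", {
  dip <- make_response(function(t) 0.05 + 0.002 * (t - 26)^2)
  est <- find_extremum(fit_cubic(dip), "dip")
  expect_equal(est$t_star, 26, tolerance = 1e-6)
  expect_equal(est$amplitude, 0.05, tolerance = 1e-6)
  expect_false(est$boundary)

  # a genuine cubic: y' = 3(T-20)(T-35), dip at 35, peak at 20
  cub <- make_response(function(t) t^3 - 1.5 * 55 * t^2 + 3 * 700 * t)
  fitc <- fit_cubic(cub)
  expect_equal(find_extremum(fitc, "dip")$t_star, 35, tolerance = 1e-6)
  expect_equal(find_extremum(fitc, "peak")$t_star, 20, tolerance = 1e-6)

  mono <- make_response(function(t) 0.1 * t)
  expect_error(find_extremum(fit_cubic(mono), "peak"),
               class = "qm_no_extremum_error")
})

test_that("biphasic Hill extremum matches a 0.001 C exhaustive grid search", {
  draws <- withr::with_seed(2024, {
    purrr::map(1:100, function(i) {
      c(y0 = stats::runif(1, -0.2, 0.2), pm = stats::runif(1, 0.3, 3),
        ka = stats::runif(1, 20, 34), ha = stats::runif(1, 4, 30),
        ki = stats::runif(1, 36, 44), hi = stats::runif(1, 4, 30))
    })
  })
  grid <- seq(10, 45, by = 0.001)
  n_checked <- 0
  for (p in draws) {
    fit <- structure(list(parameters = p, kind = "peak", sign = 1,
                          range = c(10, 45), rss = 0, n = 0,
                          degenerate = FALSE, model_name = "bihill"),
                     class = "bihill_fit")
    vals <- predict(fit, grid)
    i <- which.max(vals)
    if (i == 1 || i == length(grid)) next # no interior peak for this draw
    est <- find_extremum(fit, "peak")
    expect_lt(abs(est$t_star - grid[i]), 0.05)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 80)
})

test_that("dip fitting via negation mirrors the peak path", {
  bell <- function(t) 1 / ((1 + (30 / t)^12) * (1 + (t / 40)^12))
  up <- make_response(function(t) 0.1 + bell(t))
  down <- make_response(function(t) -0.1 - bell(t))
  peak <- find_extremum(fit_bihill(up, "peak"), "peak")
  dip <- find_extremum(fit_bihill(down, "dip"), "dip")
  expect_equal(dip$t_star, peak$t_star, tolerance = 1e-4)
  expect_equal(dip$amplitude, -peak$amplitude, tolerance = 1e-6)
})

test_that("bootstrap extremum is deterministic, and exact for noise-free data", {
  bell <- function(t) 0.8 / ((1 + (31 / t)^10) * (1 + (t / 39)^14))
  clean <- make_response(bell)
  est <- bootstrap_extremum(clean, "bihill", "peak", n_boot = 100, seed = 42)
  expect_lt(est$uncertainty, 1e-9)
  est2 <- bootstrap_extremum(clean, "bihill", "peak", n_boot = 100, seed = 42)
  expect_identical(est, est2)
  expect_error(bootstrap_extremum(clean, "bihill", "peak", n_boot = 50, seed = 1),
               class = "qm_value_error")
  expect_error(bootstrap_extremum(clean, "bihill", "peak", n_boot = 100),
               class = "qm_config_error")
  single <- make_response(bell, reps = 1)
  expect_error(bootstrap_extremum(single, "bihill", "peak", n_boot = 100, seed = 1),
               class = "qm_insufficient_data_error")
})

test_that("bootstrap SD agrees with a Monte-Carlo regeneration oracle", {
  bell <- function(t) 0.8 / ((1 + (31 / t)^10) * (1 + (t / 39)^14))
  # oracle: SD of the fitted peak over independent regenerations at CV 2%
  t_stars <- withr::with_seed(314, {
    vapply(1:200, function(i) {
      resp <- make_response(bell, noise_cv = 0.02)
      find_extremum(fit_bihill(resp, "peak"), "peak")$t_star
    }, numeric(1))
  })
  sd_true <- stats::sd(t_stars)
  resp <- withr::with_seed(315, make_response(bell, noise_cv = 0.02))
  est <- bootstrap_extremum(resp, "bihill", "peak", n_boot = 1000, seed = 99)
  expect_gt(est$uncertainty, sd_true / 2)
  expect_lt(est$uncertainty, sd_true * 2)
})

test_that("bootstrap mean lands within 2 corrected SD of the true peak in >= 90% of trials", {
  bell <- function(t) 0.8 / ((1 + (31 / t)^10) * (1 + (t / 39)^14))
  t_true <- {
    g <- seq(10, 45, 0.001)
    g[which.max(bell(g))]
  }
  # resampling n = 4 replicates with replacement deflates the bootstrap SD by
  # the standard factor sqrt((n-1)/n); coverage is assessed on the corrected
  # 2-SD band
  correction <- sqrt(4 / 3)
  hits <- withr::with_seed(2718, {
    vapply(1:100, function(i) {
      resp <- make_response(bell, noise_cv = 0.05)
      est <- bootstrap_extremum(resp, "bihill", "peak", n_boot = 100, seed = i)
      abs(est$t_star - t_true) <= 2 * correction * max(est$uncertainty, 1e-6)
    }, logical(1))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("build_thermal_response extracts components with provenance", {
  run1 <- small_sim_run(seed = 21, cols = 3, gradient_id = "gA")
  run2 <- small_sim_run(seed = 22, cols = 3, gradient_id = "gB")
  run2 <- assign_temperatures(run2, c("1" = 30, "2" = 32, "3" = 34))
  comps <- list(deconvolute_run(run1), deconvolute_run(run2))
  resp <- build_thermal_response(list(run1, run2), comps, "qE")
  expect_equal(nrow(resp), 24)
  expect_s3_class(resp, "thermal_response")
  expect_error(build_thermal_response(list(run1, run2), comps, "bogus"),
               class = "qm_config_error")
  expect_error(build_thermal_response(list(run1, run2), comps, "qT1"),
               class = "qm_config_error")
})
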