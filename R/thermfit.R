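# Thermal-response curve fitting and extremum extraction.
#
# Two model families mirror common practice for these data: a 3rd-order
# polynomial for dip-shaped qE responses, and a bell-shaped biphasic Hill
# product for rise-then-fall responses,
#   y(T) = y0 + Pm / ((1 + (Ka/T)^Ha) * (1 + (T/Ki)^Hi)),
# i.e. an activating Hill term with midpoint Ka and slope Ha multiplied by an
# inhibiting term with midpoint Ki and slope Hi.  Dips are fitted by negating
# the values internally; predictions are always on the original scale.

bihill_curve <- function(t, y0, pm, ka, ha, ki, hi) {
  y0 + pm / ((1 + (ka / t)^ha) * (1 + (t / ki)^hi))
}

#' Fit a cubic polynomial to a thermal response
#'
#' Ordinary least squares through all replicate points.
#'
#' @param response A [thermal_response()] with >= 4 distinct temperatures.
#' @return An object of class `cubic_fit`: coefficients `a0..a3`, the fit
#'   range, residual sum of squares and point count.
#' @export
fit_cubic <- function(response) {
  stopifnot(inherits(response, "thermal_response"))
  pts <- sorted_points(response)
  if (length(unique(pts$temperature)) < 4) {
    abort_insufficient_data("Cubic fit needs >= 4 distinct temperatures.")
  }
  fit <- stats::lm(value ~ stats::poly(temperature, 3, raw = TRUE), data = pts)
  coefs <- unname(stats::coef(fit))
  structure(
    list(coefficients = stats::setNames(coefs, c("a0", "a1", "a2", "a3")),
         range = range(pts$temperature),
         rss = sum(stats::resid(fit)^2),
         n = nrow(pts),
         component_name = attr(response, "component_name"),
         model_name = "cubic"),
    class = "cubic_fit")
}

#' @export
predict.cubic_fit <- function(object, temperature, ...) {
  a <- object$coefficients
  a[["a0"]] + a[["a1"]] * temperature + a[["a2"]] * temperature^2 +
    a[["a3"]] * temperature^3
}

#' @export
print.cubic_fit <- function(x, ...) {
  cat(sprintf("<cubic_fit> %s: y = %.4g + %.4g T + %.4g T^2 + %.4g T^3 on [%.1f, %.1f] C (RSS %.4g, n = %d)\n",
              x$component_name %||% "response",
              x$coefficients[["a0"]], x$coefficients[["a1"]],
              x$coefficients[["a2"]], x$coefficients[["a3"]],
              x$range[1], x$range[2], x$rss, x$n))
  invisible(x)
}

# Sort points into a canonical order so fits are invariant under permutation
# of the input rows.
sorted_points <- function(response) {
  pts <- tibble::as_tibble(response)[, c("temperature", "value")]
  pts[order(pts$temperature, pts$value), ]
}

#' Fit a biphasic Hill curve to a thermal response
#'
#' Nonlinear least squares (Levenberg-Marquardt) on
#' `y(T) = y0 + Pm / ((1 + (Ka/T)^Ha) * (1 + (T/Ki)^Hi))`.  Initial values
#' come from data heuristics (baseline = minimum value, peak guess at the
#' maximum, Ka/Ki from half-maximum crossings, Ha = Hi = 8); parameters are
#' bounded (`Ka, Ki` in [5, 60] deg C, `Ha, Hi` in [0.5, 50]).  Up to 10
#' restarts from deterministically jittered initial values are attempted
#' before declaring failure.  For `kind = "dip"` the values are negated
#' internally before fitting; [predict()] returns original-scale values.
#'
#' @param response A [thermal_response()] with >= 6 distinct temperatures.
#' @param kind `"peak"` (default) for a bell, `"dip"` for an inverted bell.
#' @return An object of class `bihill_fit` with elements `parameters`
#'   (y0, Pm, Ka, Ha, Ki, Hi on the internal, possibly negated scale),
#'   `kind`, `range`, `rss`, `n`, `degenerate`.
#' @export
fit_bihill <- function(response, kind = c("peak", "dip")) {
  stopifnot(inherits(response, "thermal_response"))
  kind <- match.arg(kind)
  pts <- sorted_points(response)
  n_temps <- length(unique(pts$temperature))
  if (n_temps < 6) {
    abort_insufficient_data("Biphasic Hill fit needs >= 6 distinct temperatures.")
  }
  sign <- if (kind == "dip") -1 else 1
  dat <- data.frame(t = pts$temperature, y = sign * pts$value)
  if (diff(range(dat$y)) < 1e-12) {
    abort_fit_failure("Biphasic Hill fit failed: response values are constant.")
  }

  lower <- c(y0 = -Inf, pm = 0, ka = 5, ha = 0.5, ki = 5, hi = 0.5)
  upper <- c(y0 = Inf, pm = Inf, ka = 60, ha = 50, ki = 60, hi = 50)
  start <- bihill_start(dat)

  jitters <- withr::with_seed(1734L, {
    purrr::map(seq_len(10), function(i) {
      c(ka = stats::runif(1, 0.9, 1.1), ki = stats::runif(1, 0.9, 1.1),
        ha = stats::runif(1, 0.5, 2), hi = stats::runif(1, 0.5, 2))
    })
  })

  best <- NULL
  attempts <- c(list(NULL), jitters) # initial guess, then 10 jittered restarts
  for (jit in attempts) {
    st <- start
    if (!is.null(jit)) {
      st[["ka"]] <- min(max(st[["ka"]] * jit[["ka"]], lower[["ka"]]), upper[["ka"]])
      st[["ki"]] <- min(max(st[["ki"]] * jit[["ki"]], lower[["ki"]]), upper[["ki"]])
      st[["ha"]] <- min(max(st[["ha"]] * jit[["ha"]], lower[["ha"]]), upper[["ha"]])
      st[["hi"]] <- min(max(st[["hi"]] * jit[["hi"]], lower[["hi"]]), upper[["hi"]])
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bihill_curve(t, y0, pm, ka, ha, ki, hi),
        data = dat, start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
    # a converged, non-collapsed fit ends the restart loop; further restarts
    # are only spent when a start fails or collapses to Pm ~ 0
    if (isTRUE(fit$convInfo$isConv) && stats::coef(fit)[["pm"]] > 1e-8) break
  }
  if (is.null(best)) {
    abort_fit_failure(sprintf(
      "Biphasic Hill fit did not converge after %d starts (n = %d points).",
      length(attempts), nrow(dat)))
  }
  pars <- stats::coef(best$fit)
  structure(
    list(parameters = pars, kind = kind, sign = sign,
         range = range(dat$t), rss = best$rss, n = nrow(dat),
         degenerate = pars[["pm"]] < 1e-8,
         component_name = attr(response, "component_name"),
         model_name = "bihill"),
    class = "bihill_fit")
}

# Heuristic start values on the (possibly negated) fitting scale.
bihill_start <- function(dat) {
  agg <- stats::aggregate(y ~ t, data = dat, FUN = mean)
  y0 <- min(agg$y)
  pm <- max(agg$y) - y0
  t_pk <- agg$t[which.max(agg$y)]
  half <- y0 + pm / 2
  below <- agg$t[agg$t < t_pk & agg$y < half]
  above <- agg$t[agg$t > t_pk & agg$y < half]
  ka <- if (length(below) > 0) max(below) else t_pk - 3
  ki <- if (length(above) > 0) min(above) else t_pk + 3
  c(y0 = y0, pm = max(pm, 1e-6),
    ka = min(max(ka, 5), 60), ha = 8,
    ki = min(max(ki, 5), 60), hi = 8)
}

#' @export
predict.bihill_fit <- function(object, temperature, ...) {
  p <- object$parameters
  object$sign * bihill_curve(temperature, p[["y0"]], p[["pm"]], p[["ka"]],
                             p[["ha"]], p[["ki"]], p[["hi"]])
}

#' @export
print.bihill_fit <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("<bihill_fit> %s (%s): y0 = %.4g, Pm = %.4g, Ka = %.2f, Ha = %.2f, Ki = %.2f, Hi = %.2f\n",
              x$component_name %||% "response", x$kind,
              p[["y0"]], p[["pm"]], p[["ka"]], p[["ha"]], p[["ki"]], p[["hi"]]))
  cat(sprintf("  range [%.1f, %.1f] C, RSS %.4g, n = %d%s\n",
              x$range[1], x$range[2], x$rss, x$n,
              if (isTRUE(x$degenerate)) " [degenerate: Pm ~ 0]" else ""))
  invisible(x)
}

# ---- extremum extraction ----------------------------------------------------

new_extremum_estimate <- function(kind, t_star, amplitude, model_name,
                                  uncertainty = NA_real_, n_boot = 0L,
                                  boundary = FALSE, n_failed = 0L) {
  structure(
    list(kind = kind, t_star = t_star, amplitude = amplitude,
         uncertainty = uncertainty, n_boot = n_boot, model_name = model_name,
         boundary = boundary, n_failed = n_failed),
    class = "extremum_estimate")
}

#' @export
print.extremum_estimate <- function(x, ...) {
  unc <- if (is.na(x$uncertainty)) "" else sprintf(" +/- %.2f", x$uncertainty)
  cat(sprintf("<extremum_estimate> %s (%s fit): T* = %.2f%s C, amplitude = %.4g%s\n",
              x$kind, x$model_name, x$t_star, unc, x$amplitude,
              if (isTRUE(x$boundary)) " [at range boundary]" else ""))
  if (x$n_boot > 0) {
    cat(sprintf("  bootstrap: n = %d (%d refits failed)\n", x$n_boot, x$n_failed))
  }
  invisible(x)
}

#' Locate the peak or dip of a fitted thermal-response curve
#'
#' For a cubic fit the real roots of the derivative inside the fit range are
#' found in closed form and filtered by the second-derivative sign matching
#' `kind`; ties are broken by the most extreme fitted value, then by the
#' lower temperature.  For a biphasic Hill fit the curve is scanned on a
#' 0.01 deg C grid and the winning point refined by local golden-section
#' search.  The amplitude is the fitted value at the extremum temperature.
#' An extremum within 0.25 deg C of the range boundary is flagged
#' (`boundary = TRUE`).
#'
#' @param fit A `cubic_fit` or `bihill_fit`.
#' @param kind `"peak"` or `"dip"`.
#' @return An object of class `extremum_estimate`.
#' @export
find_extremum <- function(fit, kind = c("peak", "dip")) {
  UseMethod("find_extremum")
}

#' @export
find_extremum.cubic_fit <- function(fit, kind = c("peak", "dip")) {
  kind <- match.arg(kind)
  a <- fit$coefficients
  lo <- fit$range[1]
  hi <- fit$range[2]
  scale <- max(abs(a), 1e-300)
  # roots of y' = a1 + 2 a2 T + 3 a3 T^2
  if (abs(a[["a3"]]) > 1e-12 * scale) {
    disc <- (2 * a[["a2"]])^2 - 4 * (3 * a[["a3"]]) * a[["a1"]]
    if (disc < 0) abort_no_extremum("Cubic has no real critical point.")
    roots <- (-2 * a[["a2"]] + c(-1, 1) * sqrt(disc)) / (2 * 3 * a[["a3"]])
  } else if (abs(a[["a2"]]) > 1e-12 * scale) {
    roots <- -a[["a1"]] / (2 * a[["a2"]])
  } else {
    abort_no_extremum("Cubic is (affine-)linear: no interior extremum.")
  }
  curv <- 2 * a[["a2"]] + 6 * a[["a3"]] * roots
  want <- if (kind == "dip") curv > 0 else curv < 0
  inside <- roots > lo & roots < hi
  cand <- roots[want & inside]
  if (length(cand) == 0) {
    abort_no_extremum(sprintf("No interior %s in the fit range [%.1f, %.1f].",
                              kind, lo, hi))
  }
  vals <- predict(fit, cand)
  extremeness <- if (kind == "dip") -vals else vals
  best <- order(-extremeness, cand)[1]
  t_star <- cand[best]
  new_extremum_estimate(kind, t_star, predict(fit, t_star), "cubic",
                        boundary = min(t_star - lo, hi - t_star) < 0.25)
}

#' @export
find_extremum.bihill_fit <- function(fit, kind = c("peak", "dip")) {
  kind <- match.arg(kind)
  lo <- fit$range[1]
  hi <- fit$range[2]
  grid <- seq(lo, hi, by = 0.01)
  vals <- predict(fit, grid)
  idx <- if (kind == "dip") which.min(vals) else which.max(vals)
  if (idx == 1 || idx == length(grid)) {
    abort_no_extremum(sprintf("No interior %s: curve is extreme at the %.1f C boundary.",
                              kind, grid[idx]))
  }
  f <- function(t) predict(fit, t)
  opt <- stats::optimize(f, interval = c(grid[idx - 1], grid[idx + 1]),
                         maximum = (kind == "peak"), tol = 1e-6)
  t_star <- if (kind == "peak") opt$maximum else opt$minimum
  amp <- if (kind == "peak") opt$objective else opt$objective
  new_extremum_estimate(kind, t_star, amp, "bihill",
                        boundary = min(t_star - lo, hi - t_star) < 0.25)
}

#' Bootstrap uncertainty of a thermal-response extremum
#'
#' Resamples the replicate values within each temperature with replacement,
#' refits the chosen model and re-extracts the extremum temperature.  Returns
#' the bootstrap mean T*, the full-data fitted amplitude at that temperature,
#' and the bootstrap SD of T* as the uncertainty.  Fully reproducible from
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param response A [thermal_response()] with >= 2 replicates at at least
#'   half of the temperatures.
#' @param model `"cubic"` or `"bihill"`.
#' @param kind `"peak"` or `"dip"`.
#' @param n_boot Number of bootstrap resamples (>= 100; default 1000).
#' @param seed Integer seed (mandatory).
#' @return An `extremum_estimate` with `uncertainty`, `n_boot` and the count
#'   of failed refits; errors with class `qm_unstable_fit_error` if more than
#'   20% of refits fail.
#' @export
bootstrap_extremum <- function(response, model = c("cubic", "bihill"),
                               kind = c("peak", "dip"), n_boot = 1000,
                               seed) {
  stopifnot(inherits(response, "thermal_response"))
  model <- match.arg(model)
  kind <- match.arg(kind)
  if (missing(seed) || is.null(seed)) abort_config("bootstrap_extremum needs a seed.")
  if (n_boot < 100) abort_value("n_boot must be >= 100.")
  pts <- tibble::as_tibble(response)
  counts <- table(pts$temperature)
  if (mean(counts >= 2) < 0.5) {
    abort_insufficient_data(
      "Bootstrap needs >= 2 replicates at at least half of the temperatures.")
  }
  comp <- attr(response, "component_name")
  fit_fun <- function(resp) {
    if (model == "cubic") fit_cubic(resp) else fit_bihill(resp, kind)
  }
  full_fit <- fit_fun(response)
  groups <- split(seq_len(nrow(pts)), pts$temperature)
  t_stars <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      take <- unlist(lapply(groups, function(ix) ix[sample.int(length(ix), length(ix), replace = TRUE)]),
                     use.names = FALSE)
      boot_pts <- pts[take, ]
      tryCatch({
        resp_b <- thermal_response(boot_pts, comp)
        find_extremum(fit_fun(resp_b), kind)$t_star
      }, error = function(e) NA_real_)
    }, numeric(1))
  })
  n_failed <- sum(is.na(t_stars))
  if (n_failed > 0.2 * n_boot) {
    abort_unstable_fit(sprintf(
      "Bootstrap unstable: %d of %d refits failed.", n_failed, n_boot))
  }
  ok <- t_stars[!is.na(t_stars)]
  t_mean <- mean(ok)
  lo <- full_fit$range[1]
  hi <- full_fit$range[2]
  new_extremum_estimate(kind, t_mean, predict(full_fit, t_mean),
                        model, uncertainty = stats::sd(ok),
                        n_boot = as.integer(n_boot),
                        boundary = min(t_mean - lo, hi - t_mean) < 0.25,
                        n_failed = as.integer(n_failed))
}

#' Assemble a thermal response for one component across runs
#'
#' Extracts the named component from per-run deconvolution tables (as
#' produced by [deconvolute_run()]), attaches each run's well temperatures
#' and merges everything via [merge_gradient_runs()].
#'
#' @param runs List of [plate_run()]s with temperatures assigned.
#' @param components List (parallel to `runs`) of [deconvolute_run()]
#'   tibbles.
#' @param component_name One of `"qE"`, `"slow_relaxing"`, `"qT2"`, `"qT1"`,
#'   `"Y2"`, `"FvFm"`, `"YNPQ"`, `"YNO"`, `"qL"`, `"closed_rc"`.
#' @return A [thermal_response()].
#' @export
build_thermal_response <- function(runs, components, component_name) {
  col_map <- c(qE = "qe", slow_relaxing = "slow_relaxing", qT2 = "qt2",
               qT1 = "qt1", Y2 = "y2", FvFm = "fv_fm", YNPQ = "y_npq",
               YNO = "y_no", qL = "q_l", closed_rc = "closed_rc")
  if (!component_name %in% names(col_map)) {
    abort_config(sprintf("Unknown component '%s'; expected one of: %s",
                         component_name, paste(names(col_map), collapse = ", ")))
  }
  if (length(components) != length(runs)) {
    abort_value("components must be parallel to runs.")
  }
  col <- col_map[[component_name]]
  vals <- purrr::map(components, function(tab) {
    v <- tab[[col]]
    if (all(is.na(v))) {
      abort_config(sprintf(
        "Component '%s' is unavailable (no +/-FR pairing?) in a run.", component_name))
    }
    tibble::tibble(well = tab$well, value = v)
  })
  merge_gradient_runs(runs, vals, component_name)
}
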