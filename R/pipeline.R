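# End-to-end orchestration: simulate and/or analyze plate runs, merge
# gradient runs per component, fit thermal responses and write a
# machine-readable summary (one row per component: peak/dip temperature,
# bootstrap SD, amplitude).

default_component_models <- function() {
  list(
    qE = list(model = "cubic", kind = "dip"),
    slow_relaxing = list(model = "bihill", kind = "peak"),
    qT2 = list(model = "bihill", kind = "peak"),
    qT2_FR = list(model = "bihill", kind = "peak"),
    qT1 = list(model = "bihill", kind = "peak"),
    Y2 = list(model = "bihill", kind = "peak"),
    FvFm = list(model = "bihill", kind = "peak"))
}

#' Pipeline run configuration
#'
#' @param mode `"simulate+analyze"` (default), `"simulate"` (write trace
#'   tables only) or `"analyze"` (read trace tables from `trace_files`).
#' @param preset Preset name (see [preset_from_table1()]) for simulation
#'   modes.
#' @param trace_files Character vector of trace CSV paths for
#'   `mode = "analyze"`.  Far-red pairing is inferred from the files'
#'   `gradient_id`/`fr_in_dark` metadata columns.
#' @param gradients Named list of column->temperature gradients (default
#'   [default_gradients()]).
#' @param components Components to map and fit (default qE, slow-relaxing,
#'   qT2 without and with far-red, and Y(II)); `"qT2_FR"` denotes the qT2
#'   response of the far-red-on runs.
#' @param models Optional named list overriding the per-component model
#'   choice, each element `list(model = "cubic"|"bihill", kind =
#'   "peak"|"dip")`.
#' @param n_boot Bootstrap resamples for the extremum uncertainty (0
#'   disables the bootstrap).
#' @param seed Integer seed; mandatory whenever simulation or bootstrapping
#'   is enabled.
#' @param kinetics A [kinetic_config()] for simulation modes.
#' @param protocol A [protocol_spec()].
#' @param fr_pairing Simulate each gradient with far-red off *and* on
#'   (enables qT1 and qT2_FR; default `TRUE`).
#' @param out_dir Output directory (created if needed).
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate+analyze", "simulate", "analyze"),
                       preset = NULL, trace_files = NULL,
                       gradients = default_gradients(),
                       components = c("qE", "slow_relaxing", "qT2", "qT2_FR", "Y2"),
                       models = NULL, n_boot = 0, seed = NULL,
                       kinetics = kinetic_config(), protocol = protocol_spec(),
                       fr_pairing = TRUE, out_dir = tempfile("quenchmap_run_")) {
  mode <- match.arg(mode)
  simulate <- mode %in% c("simulate+analyze", "simulate")
  if (simulate && is.null(preset)) abort_config("Simulation modes need a preset.")
  if (mode == "analyze" && (is.null(trace_files) || length(trace_files) == 0)) {
    abort_config("mode = 'analyze' needs trace_files.")
  }
  needs_seed <- (simulate && kinetics$noise_cv > 0) || n_boot > 0
  if (needs_seed && is.null(seed)) {
    abort_config("A seed is mandatory whenever a stochastic step (simulation noise or bootstrap) is enabled.")
  }
  known <- names(default_component_models())
  bad <- setdiff(components, known)
  if (length(bad) > 0) {
    abort_config(sprintf("Unknown component(s): %s", paste(bad, collapse = ", ")))
  }
  structure(
    list(mode = mode, preset = preset, trace_files = trace_files,
         gradients = gradients, components = components,
         models = utils::modifyList(default_component_models(), models %||% list()),
         n_boot = n_boot, seed = seed, kinetics = kinetics,
         protocol = protocol, fr_pairing = isTRUE(fr_pairing),
         out_dir = out_dir),
    class = "run_config")
}

#' Run the full measurement-to-summary pipeline
#'
#' Depending on the mode: simulates paired (far-red off/on) plate runs for
#' each gradient and/or reads trace tables, deconvolutes every well, merges
#' the gradient runs per component, fits the configured model and extracts
#' the extremum.  Writes, under `config$out_dir`: trace tables (simulate
#' modes), `components.csv` (per-well values), `response_<component>.csv`
#' tables, `fit_summary.csv` and a line-oriented `run.log` with ISO
#' timestamps recording versions, the seed and every diagnostic (negative
#' NPQ counts, dark spikes, Fm' exceedances, boundary extrema, failed fits).
#' A failed fit for one component does not abort the others.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `summary` (the fit-summary tibble),
#'   `responses`, `components`, `runs`, `status`
#'   (`"success"`/`"partial"`/`"failed"`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_msg <- function(fmt, ...) {
    line <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }
  log_msg("quenchmap %s on %s", as.character(utils::packageVersion("quenchmap")),
          R.version.string)
  log_msg("mode=%s preset=%s seed=%s n_boot=%d", config$mode,
          config$preset %||% "-", config$seed %||% "-", config$n_boot)

  # ---- acquire runs ---------------------------------------------------------
  runs <- list()
  if (config$mode %in% c("simulate", "simulate+analyze")) {
    preset <- preset_from_table1(config$preset)
    fr_states <- if (config$fr_pairing) c(FALSE, TRUE) else FALSE
    i <- 0
    for (gid in names(config$gradients)) {
      for (fr in fr_states) {
        i <- i + 1
        run_seed <- as.integer((as.double(config$seed %||% 0) * 131 + i) %% 2147483647)
        run <- simulate_plate_run(
          preset, config$gradients[[gid]], kinetics = config$kinetics,
          fr_in_dark = fr, seed = run_seed, gradient_id = gid,
          protocol = config$protocol)
        key <- paste0(gid, if (fr) "_frOn" else "_frOff")
        runs[[key]] <- run
        path <- file.path(config$out_dir, paste0("traces_", key, ".csv"))
        write_trace_table(run, path)
        log_msg("simulated %s: %d wells, far-red %s, %d Fm' exceedance(s)",
                gid, length(run$traces), if (fr) "on" else "off",
                run$n_fmp_exceedances)
      }
    }
    if (config$mode == "simulate") {
      writeLines(log_lines, file.path(config$out_dir, "run.log"))
      return(invisible(list(runs = runs, status = "success",
                            out_dir = config$out_dir)))
    }
  } else {
    for (path in config$trace_files) {
      run <- read_trace_table(path, config$protocol)
      key <- paste0(run$gradient_id, if (run$fr_in_dark) "_frOn" else "_frOff")
      if (is.null(run$well_temperature)) {
        if (!run$gradient_id %in% names(config$gradients)) {
          abort_config(sprintf(
            "Trace file %s has no temperatures and no gradient named '%s' is configured.",
            path, run$gradient_id))
        }
        run <- assign_temperatures(run, config$gradients[[run$gradient_id]])
      }
      runs[[key]] <- run
      log_msg("read %s: %d wells (far-red %s)", path, length(run$traces),
              if (run$fr_in_dark) "on" else "off")
    }
  }

  fr_off <- runs[!vapply(runs, function(r) r$fr_in_dark, logical(1))]
  fr_on <- runs[vapply(runs, function(r) r$fr_in_dark, logical(1))]

  # ---- deconvolute ----------------------------------------------------------
  pair_for <- function(run) {
    cand <- purrr::keep(fr_on, function(r) identical(r$gradient_id, run$gradient_id))
    if (length(cand) == 1) cand[[1]] else NULL
  }
  comp_off <- purrr::map(fr_off, function(r) deconvolute_run(r, pair_for(r)))
  comp_on <- purrr::map(fr_on, deconvolute_run)
  all_comp <- c(comp_off, comp_on)
  all_runs <- c(fr_off, fr_on)

  n_neg <- sum(purrr::map_int(all_comp, function(x) sum(x$n_negative_npq > 0)))
  n_spk <- sum(purrr::map_int(all_comp, function(x) sum(x$dark_spike)))
  log_msg("deconvoluted %d wells across %d run(s); wells with negative NPQ: %d; wells with dark spike: %d",
          sum(purrr::map_int(all_comp, nrow)), length(all_runs), n_neg, n_spk)

  comp_long <- purrr::map2(all_runs, all_comp, function(run, tab) {
    tidyr::pivot_longer(
      tab[, c("well", "run_id", "temperature_C", "qe", "slow_relaxing",
              "qt2", "qt1", "y2", "fv_fm", "y_npq", "y_no", "closed_rc")],
      cols = -c("well", "run_id", "temperature_C"),
      names_to = "component", values_to = "value") |>
      dplyr::mutate(fr_in_dark = run$fr_in_dark,
                    growth_temperature = run$acclimation$growth_temperature,
                    light_level = run$acclimation$light_level)
  }) |> dplyr::bind_rows()
  write_component_table(comp_long[!is.na(comp_long$value), ],
                        file.path(config$out_dir, "components.csv"))

  # ---- responses and fits ---------------------------------------------------
  summary_rows <- list()
  responses <- list()
  any_ok <- FALSE
  any_fail <- FALSE
  for (comp in config$components) {
    spec <- config$models[[comp]]
    use_fr_on <- identical(comp, "qT2_FR")
    use_runs <- if (use_fr_on) fr_on else fr_off
    use_comp <- if (use_fr_on) comp_on else comp_off
    base_name <- if (use_fr_on) "qT2" else comp
    row <- tibble::tibble(
      component = comp, model = spec$model, kind = spec$kind,
      t_star = NA_real_, t_star_sd = NA_real_, amplitude = NA_real_,
      n_boot = as.integer(config$n_boot), boundary = NA, status = "failed",
      message = NA_character_)
    res <- tryCatch({
      if (length(use_runs) == 0) abort_config(sprintf("No runs available for %s.", comp))
      resp <- build_thermal_response(use_runs, use_comp, base_name)
      attr(resp, "component_name") <- comp
      responses[[comp]] <- resp
      readr::write_csv(
        tibble::as_tibble(resp),
        file.path(config$out_dir, paste0("response_", comp, ".csv")),
        progress = FALSE)
      est <- if (config$n_boot > 0) {
        boot_seed <- as.integer((as.double(config$seed) * 7 +
                                   match(comp, config$components)) %% 2147483647)
        bootstrap_extremum(resp, model = spec$model, kind = spec$kind,
                           n_boot = config$n_boot, seed = boot_seed)
      } else {
        fit <- if (spec$model == "cubic") fit_cubic(resp) else fit_bihill(resp, spec$kind)
        find_extremum(fit, spec$kind)
      }
      est
    }, error = function(e) e)
    if (inherits(res, "error")) {
      any_fail <- TRUE
      row$message <- conditionMessage(res)
      log_msg("FIT FAILED [%s]: %s", comp, conditionMessage(res))
    } else {
      any_ok <- TRUE
      row$t_star <- res$t_star
      row$t_star_sd <- res$uncertainty
      row$amplitude <- res$amplitude
      row$boundary <- res$boundary
      row$status <- "ok"
      if (isTRUE(res$boundary)) log_msg("WARNING [%s]: extremum at fit-range boundary", comp)
      log_msg("fitted %s (%s, %s): T* = %.2f C, amplitude = %.4g", comp,
              spec$model, spec$kind, res$t_star, res$amplitude)
    }
    summary_rows[[comp]] <- row
  }
  summary <- dplyr::bind_rows(summary_rows)
  acc <- all_runs[[1]]$acclimation
  summary$light_level <- acc$light_level
  summary$growth_temperature <- acc$growth_temperature
  readr::write_csv(summary, file.path(config$out_dir, "fit_summary.csv"),
                   progress = FALSE)
  status <- if (!any_fail) "success" else if (any_ok) "partial" else "failed"
  log_msg("pipeline status: %s", status)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(summary = summary, responses = responses,
                 components = all_comp, runs = all_runs,
                 status = status, out_dir = config$out_dir))
}

#' Plot a thermal response with an optional fitted curve
#'
#' @param response A [thermal_response()].
#' @param fit Optional `cubic_fit` or `bihill_fit` drawn over the points.
#' @return A ggplot object.
#' @export
plot_thermal_response <- function(response, fit = NULL) {
  df <- tibble::as_tibble(response)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$temperature, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Temperature (°C)",
                  y = attr(response, "component_name") %||% "value") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- seq(min(df$temperature), max(df$temperature), length.out = 400)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(temperature = grid, value = predict(fit, grid)),
      colour = "firebrick")
  }
  p
}
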