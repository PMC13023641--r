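#' Read a scenario configuration
#'
#' Loads a YAML scenario file (or accepts an equivalent list) describing the
#' coil, excitation, drive stage, materials and pipeline stages. Angles may
#' be given in degrees with an explicit \code{_deg} key suffix and are
#' converted to radians on load; all other quantities are SI with the unit
#' in the key name.
#'
#' Recognised sections: \code{coil} (\code{alpha_deg} or \code{alpha_rad},
#' \code{s1_m}, \code{s2_m}, \code{n_turns}, \code{current_rms_a});
#' \code{waveform} (\code{freq_hz}, \code{duty}, \code{polarity},
#' \code{rise_time_s}); \code{drive} (\code{v_supply}, \code{inductance_h},
#' \code{r_series_ohm}); \code{field} (\code{grid}: per-axis
#' \code{[min, max, n]}, \code{roi}); \code{synthetic} (\code{preset},
#' \code{n_trials}, \code{duration_s}); \code{estimate}
#' (\code{heat_capacity_c}, \code{window_s}, \code{c_interval});
#' \code{validate} (\code{measured}: \code{"reference-0.75A"} or a CSV path
#' with columns time_s, mean[, sd]); plus top-level \code{seed} and
#' \code{out_dir}.
#'
#' @param config YAML file path or a config list.
#' @return The config as a named list (class \code{thermosar_config}).
#' @export
read_scenario <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop_thermosar("config must be a YAML file path or a list",
                   "thermosar_config_error")
  }
  structure(config, class = c("thermosar_config", "list"))
}

.require_keys <- function(section, keys, where) {
  missing <- setdiff(keys, names(section))
  if (length(missing) > 0) {
    stop_thermosar(
      sprintf("config section '%s' is missing key(s): %s", where,
              paste(missing, collapse = ", ")),
      "thermosar_config_error")
  }
}

#' Build a coil geometry from a config section
#'
#' @param coil list with \code{alpha_deg} or \code{alpha_rad}, \code{s1_m},
#'   \code{s2_m}, \code{n_turns} and optionally \code{current_rms_a}.
#' @return A \code{\link{coil_geometry}}.
#' @export
coil_from_config <- function(coil) {
  .require_keys(coil, c("s1_m", "s2_m", "n_turns"), "coil")
  alpha <- if (!is.null(coil$alpha_rad)) coil$alpha_rad else {
    .require_keys(coil, "alpha_deg", "coil")
    coil$alpha_deg * pi / 180
  }
  coil_geometry(alpha, coil$s1_m, coil$s2_m, coil$n_turns,
                coil$current_rms_a %||% 1)
}

#' Default fixture coil geometry
#'
#' The fabricated coil's half-angle and slant bounds are not part of the
#' bundled measurement summaries, so field results tied to geometry are
#' fixture-dependent. This documented default (alpha = 45 deg,
#' s in [0.02, 0.12] m, N = 40, Irms = 0.75 A) is used in examples and
#' tests.
#'
#' @return A \code{\link{coil_geometry}}.
#' @export
fixture_coil <- function() {
  coil_geometry(pi / 4, 0.02, 0.12, 40, 0.75)
}

#' Run the configured analysis pipeline
#'
#' Executes the configured stages in order (\code{field},
#' \code{synthetic}, \code{estimate}, \code{validate}; each runs only if
#' its section is present), writes CSV/JSON outputs under \code{out_dir}
#' when one is given, and returns the report bundle. All randomness derives
#' from the top-level \code{seed}, so re-running an identical config is
#' bit-reproducible.
#'
#' @param config YAML path or config list (see \code{\link{read_scenario}}).
#' @return List (class \code{thermosar_report}) with one entry per executed
#'   stage plus \code{resolved} (seed and defaults actually used).
#' @export
run_pipeline <- function(config) {
  cfg <- read_scenario(config)
  seed <- cfg$seed %||% 1L
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  report <- list(resolved = list(seed = seed))
  emit <- function(obj, file, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, file))
  }

  if (!is.null(cfg$field)) {
    geo <- tryCatch(coil_from_config(cfg$field$coil %||% cfg$coil),
                    error = function(e) {
                      stop_thermosar(paste("stage 'field':",
                                           conditionMessage(e)),
                                     "thermosar_stage_error")
                    })
    gs <- cfg$field$grid
    axis_seq <- function(v) seq(v[[1]], v[[2]], length.out = v[[3]])
    grid <- field_grid(geo, list(x = axis_seq(gs$x), y = axis_seq(gs$y),
                                 z = axis_seq(gs$z)),
                       segments_per_turn =
                         cfg$field$segments_per_turn %||% 200)
    report$field <- list(
      n_nodes = nrow(grid), n_masked = sum(grid$masked),
      bmag_range_T = unname(range(grid$Bmag[!grid$masked])))
    if (!is.null(cfg$field$roi)) {
      report$field$roi_range_T <- unname(roi_field_range(grid, cfg$field$roi))
    }
    emit(grid, "field_grid.csv", write_field_grid)
  }

  trials <- NULL
  if (!is.null(cfg$synthetic)) {
    sy <- cfg$synthetic
    .require_keys(sy, "preset", "synthetic")
    trials <- generate_synthetic(sy$preset, seed = seed,
                                 n_trials = sy$n_trials %||% 10,
                                 duration = sy$duration_s %||% 3600)
    agg <- aggregate_trials(trials)
    report$synthetic <- list(preset = sy$preset, seed = seed,
                             n_trials = trials$n_trials,
                             aggregated = agg)
    emit(trials, "trials.csv", write_trial_set)
    emit(agg, "aggregated.csv",
         function(x, p) utils::write.csv(x, p, row.names = FALSE))
  }

  if (!is.null(cfg$estimate)) {
    es <- cfg$estimate
    .require_keys(es, "heat_capacity_c", "estimate")
    if (!is.null(es$series_csv)) {
      ser <- utils::read.csv(es$series_csv)
      times <- ser$time_s
      means <- ser$mean
    } else if (!is.null(trials)) {
      agg <- aggregate_trials(trials)
      times <- agg$time_s
      means <- agg$mean
    } else {
      stop_thermosar(
        "stage 'estimate' needs series_csv or a preceding synthetic stage",
        "thermosar_stage_error")
    }
    win <- unlist(es$window_s %||% c(0, 1200))
    sl <- initial_slope(times, means, window = win)
    est <- estimate_sar_eff(sl, es$heat_capacity_c)
    report$estimate <- list(
      slope_K_per_s = sl$slope, rms_residual_K = sl$rms_residual,
      sar_eff_W_per_kg = est$sar_eff,
      sar_eff_display = est$sar_eff_display,
      stabilization_time_s = stabilization_time(times, means))
    if (!is.null(es$c_interval)) {
      sens <- sensitivity(sl$slope, es$heat_capacity_c,
                          unlist(es$c_interval))
      report$estimate$sensitivity_percent <- sens$percent
      report$estimate$sar_range_W_per_kg <- unname(sens$sar_range)
    }
  }

  if (!is.null(cfg$validate)) {
    va <- cfg$validate
    meas <- if (identical(va$measured, "reference-0.75A")) {
      rs <- reference_series("0.75A")
      data.frame(time_s = rs$time_s, mean = rs$implant_mean,
                 sd = rs$implant_sd)
    } else if (is.character(va$measured)) {
      utils::read.csv(va$measured)
    } else if (!is.null(trials)) {
      agg <- aggregate_trials(trials)
      data.frame(time_s = agg$time_s, mean = agg$mean, sd = agg$sd)
    } else {
      stop_thermosar("stage 'validate' is missing 'measured'",
                     "thermosar_stage_error")
    }
    mass_m <- va$mass_m %||% 0.1
    c_heat <- va$heat_capacity_c %||% 500
    cal <- calibrate_lumped(meas$time_s, meas$mean, mass_m = mass_m,
                            heat_capacity_c = c_heat, method = "ls")
    tfine <- seq(min(meas$time_s), max(meas$time_s), length.out = 361)
    vm <- validate_model(tfine, cal$curve(tfine), meas$time_s, meas$mean,
                         meas_sd = meas$sd)
    report$validate <- list(metrics = unclass(vm),
                            lumped_fit = cal[c("p_abs", "loss_hA",
                                               "plateau", "tau")])
    emit(vm, "validation.json", write_metrics)
  }

  if (length(report) == 1) {
    stop_thermosar("config enables no pipeline stage", "thermosar_config_error")
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(.report_jsonable(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(report, class = c("thermosar_report", "list"))
}

.report_jsonable <- function(x) {
  if (is.data.frame(x)) return(as.list(x))
  if (is.list(x)) return(lapply(x, .report_jsonable))
  x
}
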