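#' Infrared camera measurement model
#'
#' Measurement-chain description of the IR thermography readout: additive
#' Gaussian camera noise (thermal sensitivity), display quantization
#' (minimum temperature resolution, applied at readout after noise), the
#' sampling interval, and an optional emissivity bias. Noise SD and display
#' resolution are modeled as distinct effects.
#'
#' @param noise_sd camera noise SD in K (default 0.05).
#' @param display_resolution display quantization step in K (default 0.1);
#'   set 0 to disable quantization.
#' @param sampling_interval s between readings (default 600).
#' @param emissivity_bias additive bias in K (default 0).
#' @param noise_dist \code{"gaussian"} (default) or \code{"t4"}
#'   (heavy-tailed, Student t with 4 df scaled to \code{noise_sd}).
#' @return An object of class \code{camera_model}.
#' @export
camera_model <- function(noise_sd = 0.05, display_resolution = 0.1,
                         sampling_interval = 600, emissivity_bias = 0,
                         noise_dist = c("gaussian", "t4")) {
  noise_dist <- match.arg(noise_dist)
  if (noise_sd < 0 || display_resolution < 0) {
    stop_thermosar("noise_sd and display_resolution must be >= 0",
                   "thermosar_validation_error")
  }
  structure(
    list(noise_sd = noise_sd, display_resolution = display_resolution,
         sampling_interval = sampling_interval,
         emissivity_bias = emissivity_bias, noise_dist = noise_dist),
    class = "camera_model"
  )
}

# round half away from zero to a resolution; res = 0 disables
.quantize <- function(x, res) {
  if (res <= 0) return(x)
  sign(x) * floor(abs(x) / res + 0.5) * res
}

.camera_noise <- function(camera, n) {
  if (camera$noise_sd == 0) return(rep(0, n))
  if (camera$noise_dist == "t4") {
    stats::rt(n, df = 4) * camera$noise_sd / sqrt(2)  # t4 variance = 2
  } else {
    stats::rnorm(n, sd = camera$noise_sd)
  }
}

#' Noise-free lumped thermal response curve
#'
#' First-order truth curve used by the synthetic generator:
#' \code{dT(t) = (P/hA)(1 - exp(-hA t / (m c)))}; with \code{loss_hA = 0}
#' it degenerates to the linear rise \code{P t / (m c)}.
#'
#' @param p_abs absorbed power in W.
#' @param mass_m mass in kg, > 0.
#' @param heat_capacity_c J/(kg K), > 0.
#' @param loss_hA W/K, >= 0.
#' @param times evaluation times in s.
#' @return Temperature rise in K at \code{times}.
#' @export
true_response <- function(p_abs, mass_m, heat_capacity_c, loss_hA, times) {
  if (mass_m <= 0 || heat_capacity_c <= 0) {
    stop_thermosar("mass and heat capacity must be > 0",
                   "thermosar_validation_error")
  }
  mc <- mass_m * heat_capacity_c
  if (loss_hA == 0) {
    p_abs * times / mc
  } else {
    (p_abs / loss_hA) * (1 - exp(-loss_hA * times / mc))
  }
}

#' Simulate repeated infrared-thermography trials
#'
#' Generates a repeated-trial measurement set with the structure of the
#' study protocol: per trial, the exposed-channel reading is
#' \code{truth(t) + drift(t) + noise}, quantized at readout, and converted
#' to a temperature change by subtracting the (equally quantized) initial
#' reading; a co-located non-exposed reference channel sees the same drift
#' (shared within a trial -- the idealization the environmental correction
#' exploits) plus its own independent noise. Ambient drift is a Gaussian
#' random walk per sampling step with an optional linear component.
#'
#' @param times sampling times in s (first element is the baseline).
#' @param truth noise-free temperature-rise curve at \code{times} (K).
#' @param camera a \code{\link{camera_model}}.
#' @param drift_spec list: \code{sd_per_step} (K, default 0.05) and
#'   \code{linear_per_s} (K/s, default 0).
#' @param n_trials number of repeated trials (default 10).
#' @param seed integer seed; identical seed gives bit-identical output.
#' @return An object of class \code{trial_set}: list with \code{times},
#'   \code{exposed} and \code{reference} (n_trials x n_times matrices of
#'   quantized temperature changes, K), \code{exposed_raw} and
#'   \code{reference_raw} (pre-quantization), \code{drift_truth}
#'   (n_trials x n_times), plus \code{truth}, \code{camera}, \code{seed}.
#' @export
simulate_trials <- function(times, truth, camera = camera_model(),
                            drift_spec = list(sd_per_step = 0.05,
                                              linear_per_s = 0),
                            n_trials = 10, seed = 1L) {
  stopifnot(length(times) == length(truth), n_trials >= 1)
  if (abs(truth[1]) > 1e-12) {
    stop_thermosar("truth curve must start at 0 (baseline-subtracted)",
                   "thermosar_validation_error")
  }
  nt <- length(times)
  sd_step <- drift_spec$sd_per_step %||% 0.05
  lin <- drift_spec$linear_per_s %||% 0
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  mk <- function() matrix(NA_real_, n_trials, nt)
  exposed <- mk(); reference <- mk()
  exposed_raw <- mk(); reference_raw <- mk()
  drift_truth <- mk()
  res <- camera$display_resolution
  for (tr in seq_len(n_trials)) {
    steps <- if (sd_step > 0) stats::rnorm(nt - 1, sd = sd_step) else
      rep(0, nt - 1)
    drift <- c(0, cumsum(steps)) + lin * (times - times[1])
    eps_e <- .camera_noise(camera, nt)
    eps_r <- .camera_noise(camera, nt)
    read_e <- truth + drift + eps_e + camera$emissivity_bias
    read_r <- drift + eps_r + camera$emissivity_bias
    exposed[tr, ] <- .quantize(read_e, res) - .quantize(read_e[1], res)
    reference[tr, ] <- .quantize(read_r, res) - .quantize(read_r[1], res)
    exposed_raw[tr, ] <- read_e - read_e[1]
    reference_raw[tr, ] <- read_r - read_r[1]
    drift_truth[tr, ] <- drift
  }
  structure(
    list(times = times, n_trials = n_trials,
         exposed = exposed, reference = reference,
         exposed_raw = exposed_raw, reference_raw = reference_raw,
         drift_truth = drift_truth, truth = truth, camera = camera,
         drift_spec = list(sd_per_step = sd_step, linear_per_s = lin),
         seed = seed),
    class = "trial_set"
  )
}

#' Environmental correction against a non-exposed reference
#'
#' Pointwise subtraction of the reference-channel temperature change from
#' the exposed-channel change, removing ambient drift shared by the two
#' channels.
#'
#' @param exposed exposed-channel temperature changes: numeric vector or
#'   trials x times matrix (K).
#' @param reference reference-channel changes with the same shape/time axis.
#' @return Corrected changes, same shape as \code{exposed}.
#' @export
environmental_correction <- function(exposed, reference) {
  de <- dim(exposed) %||% length(exposed)
  dr <- dim(reference) %||% length(reference)
  if (!identical(de, dr)) {
    stop_thermosar("exposed and reference time axes do not match",
                   "thermosar_domain_error")
  }
  exposed - reference
}

#' Aggregate repeated trials to per-time mean and SD
#'
#' @param trials a \code{\link{trial_set}}.
#' @param corrected apply \code{\link{environmental_correction}} per trial
#'   before aggregating (default TRUE).
#' @param use_raw aggregate the pre-quantization channels (default FALSE).
#' @return Data frame with \code{time_min}, \code{time_s}, \code{mean} and
#'   \code{sd} (unbiased sample SD) per time point.
#' @export
aggregate_trials <- function(trials, corrected = TRUE, use_raw = FALSE) {
  stopifnot(inherits(trials, "trial_set"))
  if (trials$n_trials < 2) {
    stop_thermosar("sample SD needs at least 2 trials",
                   "thermosar_domain_error")
  }
  ex <- if (use_raw) trials$exposed_raw else trials$exposed
  rf <- if (use_raw) trials$reference_raw else trials$reference
  m <- if (corrected) environmental_correction(ex, rf) else ex
  data.frame(time_min = trials$times / 60, time_s = trials$times,
             mean = colMeans(m), sd = apply(m, 2, stats::sd))
}

#' Synthetic-measurement presets
#'
#' Generator presets reproducing the measurement conditions of the exposure
#' experiment (10-min sampling, 60-min duration, n = 10 trials, camera
#' noise SD 0.05 K, display resolution 0.1 K, shared ambient drift with a
#' non-exposed reference channel):
#' \describe{
#'   \item{\code{implant-0.75A}}{steel implant under 0.75 A, 10 kHz drive:
#'     first-order truth anchored at initial slope 4.44e-3 K/s and plateau
#'     0.45 K (c = 500 J/(kg K), m = 0.1 kg).}
#'   \item{\code{nonimplant-0.75A}}{resin phantom: slope 5.55e-4 K/s,
#'     plateau 0.05 K (c = 1300 J/(kg K), m = 0.3 kg).}
#'   \item{\code{implant-0.1A}}{drive current reduced 0.75 -> 0.1 A; eddy
#'     power scales with I^2, so the truth amplitude scales by
#'     (0.1/0.75)^2.}
#'   \item{\code{control}}{no excitation: truth identically zero,
#'     fluctuation-only.}
#' }
#' The returned \code{truth_sar_window} is the generator's operational
#' ground truth for parameter-recovery checks: the heat capacity times the
#' OLS slope of the noise-free truth curve at the sampling times inside the
#' default estimation window (0--20 min) -- the estimator's own definition
#' applied to noise-free data.
#'
#' @param name preset name.
#' @param duration exposure duration in s (default 3600).
#' @param camera a \code{\link{camera_model}}.
#' @param slope_window SAReff estimation window in s used to define the
#'   window-referenced truth (default \code{c(0, 1200)}).
#' @return List with \code{times}, \code{truth}, \code{heat_capacity_c},
#'   \code{p_abs}, \code{mass_m}, \code{loss_hA}, \code{drift_spec},
#'   \code{truth_sar_window} and \code{truth_sar_initial} (c x initial
#'   slope of the truth curve).
#' @export
thermography_preset <- function(name = c("implant-0.75A", "nonimplant-0.75A",
                                         "implant-0.1A", "control"),
                                duration = 3600, camera = camera_model(),
                                slope_window = c(0, 1200)) {
  name <- match.arg(name)
  times <- seq(0, duration, by = camera$sampling_interval)
  par <- switch(name,
    "implant-0.75A" = list(c = 500, m = 0.1, slope = 4.44e-3,
                           plateau = 0.45),
    "nonimplant-0.75A" = list(c = 1300, m = 0.3, slope = 5.55e-4,
                              plateau = 0.05),
    "implant-0.1A" = list(c = 500, m = 0.1,
                          slope = 4.44e-3 * (0.1 / 0.75)^2,
                          plateau = 0.45 * (0.1 / 0.75)^2),
    "control" = list(c = 500, m = 0.1, slope = 0, plateau = 0))
  mc <- par$c * par$m
  if (par$slope == 0) {
    p_abs <- 0
    loss_hA <- 0
    truth <- rep(0, length(times))
  } else {
    cal <- calibrate_lumped(mass_m = par$m, heat_capacity_c = par$c,
                            method = "anchor", slope = par$slope,
                            plateau = par$plateau)
    p_abs <- cal$p_abs
    loss_hA <- cal$loss_hA
    truth <- true_response(p_abs, par$m, par$c, loss_hA, times)
  }
  in_win <- times >= slope_window[1] & times <= slope_window[2]
  sl_win <- if (sum(in_win) >= 2 && any(truth != 0)) {
    unname(stats::coef(stats::lm(truth[in_win] ~ times[in_win]))[2])
  } else 0
  list(name = name, times = times, truth = truth,
       heat_capacity_c = par$c, mass_m = par$m,
       p_abs = p_abs, loss_hA = loss_hA,
       drift_spec = list(sd_per_step = 0.05, linear_per_s = 0),
       camera = camera, slope_window = slope_window,
       truth_sar_window = par$c * sl_win,
       truth_sar_initial = par$c * par$slope)
}

#' Generate a synthetic trial set from a preset
#'
#' Convenience wrapper: builds the preset truth curve and simulates the
#' repeated trials.
#'
#' @inheritParams thermography_preset
#' @param seed integer seed.
#' @param n_trials trials per set (default 10).
#' @return A \code{\link{simulate_trials}} result with the preset stored in
#'   \code{$preset}.
#' @export
generate_synthetic <- function(name = "implant-0.75A", seed = 1L,
                               n_trials = 10, duration = 3600,
                               camera = camera_model()) {
  preset <- thermography_preset(name, duration = duration, camera = camera)
  ts <- simulate_trials(preset$times, preset$truth, camera = camera,
                        drift_spec = preset$drift_spec,
                        n_trials = n_trials, seed = seed)
  ts$preset <- preset
  ts
}

#' Write a trial set as long-format CSV with a JSON truth sidecar
#'
#' @param trials a \code{trial_set}.
#' @param path output CSV path (columns: sample_id, trial, time_s,
#'   delta_t_K, channel); the truth parameters go to a \code{.json} sidecar.
#' @param sample_id identifier written to the CSV (default the preset name
#'   if present).
#' @return Invisibly, the CSV path.
#' @export
write_trial_set <- function(trials, path, sample_id = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  sample_id <- sample_id %||% trials$preset$name %||% "sample"
  long <- function(mat, channel) {
    data.frame(sample_id = sample_id,
               trial = rep(seq_len(nrow(mat)), times = ncol(mat)),
               time_s = rep(trials$times, each = nrow(mat)),
               delta_t_K = as.vector(mat),
               channel = channel)
  }
  out <- rbind(long(trials$exposed, "exposed"),
               long(trials$reference, "reference"))
  utils::write.csv(out, path, row.names = FALSE)
  meta <- list(seed = trials$seed, n_trials = trials$n_trials,
               camera = unclass(trials$camera),
               drift_spec = trials$drift_spec,
               truth = trials$truth, times = trials$times)
  if (!is.null(trials$preset)) {
    meta$preset <- trials$preset[c("name", "heat_capacity_c", "mass_m",
                                   "p_abs", "loss_hA", "truth_sar_window",
                                   "truth_sar_initial")]
  }
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
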