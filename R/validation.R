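#' Model-vs-measurement agreement metrics
#'
#' Root-mean-square error, mean absolute error, maximum absolute error and
#' the Pearson correlation coefficient between a measured and a predicted
#' series. \code{mae <= rmse <= maxae} holds on all inputs.
#'
#' @param measured,predicted numeric vectors of equal length.
#' @return Metric value (K for the error metrics).
#' @name agreement_metrics
NULL

.check_pair <- function(measured, predicted, min_n = 1) {
  if (length(measured) != length(predicted)) {
    stop_thermosar("measured and predicted series differ in length",
                   "thermosar_domain_error")
  }
  if (length(measured) < min_n) {
    stop_thermosar("series too short", "thermosar_domain_error")
  }
}

#' @rdname agreement_metrics
#' @export
rmse <- function(measured, predicted) {
  .check_pair(measured, predicted)
  sqrt(mean((measured - predicted)^2))
}

#' @rdname agreement_metrics
#' @export
mae <- function(measured, predicted) {
  .check_pair(measured, predicted)
  mean(abs(measured - predicted))
}

#' @rdname agreement_metrics
#' @export
maxae <- function(measured, predicted) {
  .check_pair(measured, predicted)
  max(abs(measured - predicted))
}

#' @rdname agreement_metrics
#' @export
pearson_r <- function(measured, predicted) {
  .check_pair(measured, predicted, min_n = 2)
  if (stats::sd(measured) == 0 || stats::sd(predicted) == 0) {
    stop_thermosar("correlation undefined for a constant series",
                   "thermosar_degenerate_error")
  }
  stats::cor(measured, predicted)
}

#' Validate a simulated temperature curve against measured means
#'
#' Resamples the simulated curve at the measured sampling times (linear
#' interpolation; the simulated curve must cover the measured span) and
#' computes the agreement metrics. The baseline point (t = 0, exactly zero
#' in both series by construction) is included in the comparison by
#' default; \code{include_baseline = FALSE} drops it.
#'
#' @param sim_times,sim_values simulated curve (s, K).
#' @param meas_times,meas_values measured aggregated means (s, K).
#' @param meas_sd optional per-time SD of the measured means (K), used for
#'   the peak summary.
#' @param include_baseline include the t = 0 point (default TRUE).
#' @return An object of class \code{validation_metrics}: list with
#'   \code{rmse}, \code{mae}, \code{maxae}, \code{pearson_r},
#'   \code{n_points}, \code{peak_delta_t} (measured peak mean) and
#'   \code{peak_delta_t_sd} (SD at the peak time, if supplied).
#' @export
validate_model <- function(sim_times, sim_values, meas_times, meas_values,
                           meas_sd = NULL, include_baseline = TRUE) {
  if (min(meas_times) < min(sim_times) - 1e-9 ||
      max(meas_times) > max(sim_times) + 1e-9) {
    stop_thermosar("simulated curve does not cover the measured time span",
                   "thermosar_domain_error")
  }
  pred <- stats::approx(sim_times, sim_values, xout = meas_times)$y
  keep <- if (include_baseline) rep(TRUE, length(meas_times)) else
    meas_times > min(meas_times)
  y <- meas_values[keep]
  yh <- pred[keep]
  ipk <- which.max(meas_values)
  structure(
    list(rmse = rmse(y, yh), mae = mae(y, yh), maxae = maxae(y, yh),
         pearson_r = pearson_r(y, yh), n_points = length(y),
         peak_delta_t = meas_values[ipk],
         peak_delta_t_sd = if (!is.null(meas_sd)) meas_sd[ipk] else NA_real_,
         include_baseline = include_baseline),
    class = "validation_metrics"
  )
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat(sprintf("RMSE %.2f K | MAE %.2f K | MaxAE %.2f K | r %.2f (n = %d)\n",
              x$rmse, x$mae, x$maxae, x$pearson_r, x$n_points))
  cat(sprintf("Peak dT %.2f K%s\n", x$peak_delta_t,
              if (is.na(x$peak_delta_t_sd)) "" else
                sprintf(" +/- %.2f K", x$peak_delta_t_sd)))
  invisible(x)
}

#' Serialize validation metrics to JSON and back
#'
#' @param metrics a \code{validation_metrics}.
#' @param path JSON output path.
#' @return \code{write_metrics}: the path, invisibly. \code{read_metrics}:
#'   the re-parsed \code{validation_metrics}.
#' @export
write_metrics <- function(metrics, path) {
  jsonlite::write_json(unclass(metrics), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$peak_delta_t_sd <- x$peak_delta_t_sd %||% NA_real_
  structure(x, class = "validation_metrics")
}
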