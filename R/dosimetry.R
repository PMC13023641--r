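#' Initial temperature-rise slope
#'
#' Slope of the initial linear segment of a temperature-rise series, the
#' input to the lumped-capacitance SAReff estimate. The default is an
#' ordinary-least-squares fit over a fixed window (0--20 min, the regime in
#' which internal energy storage dominates conduction and boundary losses);
#' a two-point mode uses only the window endpoints.
#'
#' @param times sample times in s.
#' @param delta_t temperature rise in K, same length.
#' @param window length-2 numeric: fit window \code{(t_start, t_end)} in s
#'   (default \code{c(0, 1200)}).
#' @param mode \code{"ols"} (default) or \code{"two_point"}.
#' @return List with \code{slope} (K/s), \code{intercept} (K),
#'   \code{window_used}, \code{n_points} and \code{rms_residual} (K; fit
#'   diagnostic so callers can reject nonlinear windows; \code{NA} for fewer
#'   than 3 points).
#' @examples
#' initial_slope(c(0, 90), c(0, 0.4))$slope  # 4.44e-3 K/s
#' @export
initial_slope <- function(times, delta_t, window = c(0, 1200),
                          mode = c("ols", "two_point")) {
  mode <- match.arg(mode)
  stopifnot(length(times) == length(delta_t))
  sel <- times >= window[1] & times <= window[2]
  t_w <- times[sel]
  y_w <- delta_t[sel]
  if (length(t_w) < 2) {
    stop_thermosar("need at least 2 samples inside the window",
                   "thermosar_domain_error")
  }
  if (diff(range(t_w)) == 0) {
    stop_thermosar("window spans zero time", "thermosar_domain_error")
  }
  if (mode == "two_point") {
    i0 <- which.min(t_w)
    i1 <- which.max(t_w)
    slope <- (y_w[i1] - y_w[i0]) / (t_w[i1] - t_w[i0])
    intercept <- y_w[i0] - slope * t_w[i0]
    resid <- y_w - (intercept + slope * t_w)
  } else {
    fit <- stats::lm(y_w ~ t_w)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    resid <- stats::residuals(fit)
  }
  list(slope = slope, intercept = intercept,
       window_used = c(t_w[which.min(t_w)], t_w[which.max(t_w)]),
       n_points = length(t_w),
       rms_residual = if (length(t_w) > 2) sqrt(mean(resid^2)) else NA_real_)
}

#' Effective SAR from the initial temperature slope
#'
#' Lumped-capacitance estimate \code{SAReff = c dT/dt}: with boundary losses
#' negligible at early times, \code{m c dT/dt ~ P_abs}, so the slope of the
#' initial temperature rise divided into the heat capacity gives the
#' absorbed power per unit mass. The estimate is exactly linear in both the
#' slope and the heat capacity; density cancels through the
#' mass-normalized definition.
#'
#' @param slope initial temperature-rise rate in K/s (may carry attributes
#'   from \code{\link{initial_slope}}).
#' @param heat_capacity_c specific heat capacity in J/(kg K), > 0.
#' @param window optional provenance window \code{(t_start, t_end)} in s.
#' @return An object of class \code{sar_estimate}: list with
#'   \code{slope_dTdt}, \code{heat_capacity_c}, \code{sar_eff} (W/kg),
#'   \code{sar_eff_display} (2 significant figures), \code{cooling}
#'   (TRUE when the slope is negative) and \code{window_used}.
#' @examples
#' estimate_sar_eff(4.44e-3, 500)$sar_eff_display  # 2.2 W/kg
#' @export
estimate_sar_eff <- function(slope, heat_capacity_c, window = NULL) {
  if (heat_capacity_c <= 0) {
    stop_thermosar("heat_capacity_c must be > 0", "thermosar_validation_error")
  }
  if (is.list(slope)) {
    window <- window %||% slope$window_used
    slope <- slope$slope
  }
  sar <- heat_capacity_c * slope
  structure(
    list(slope_dTdt = slope, heat_capacity_c = heat_capacity_c,
         sar_eff = sar, sar_eff_display = signif(sar, 2),
         cooling = slope < 0, window_used = window),
    class = "sar_estimate"
  )
}

#' @export
print.sar_estimate <- function(x, ...) {
  cat(sprintf("SAReff = %.3g W/kg (display: %g; c = %g J/(kg K), dT/dt = %.3g K/s)%s\n",
              x$sar_eff, x$sar_eff_display, x$heat_capacity_c, x$slope_dTdt,
              if (isTRUE(x$cooling)) " [cooling]" else ""))
  invisible(x)
}

#' Heat-capacity sensitivity of the SAReff estimate
#'
#' Because \code{SAReff = c dT/dt} is linear in \code{c}, an uncertainty
#' interval on the heat capacity maps directly onto the estimate. Reports
#' the maximum relative deviation of the interval ends from the nominal
#' value (in percent) and the corresponding SAR range.
#'
#' @param slope initial slope in K/s.
#' @param c_nominal nominal heat capacity in J/(kg K).
#' @param c_interval length-2 numeric \code{c(lo, hi)} containing
#'   \code{c_nominal}.
#' @return List with \code{percent} (max relative deviation x 100) and
#'   \code{sar_range} (W/kg, \code{lo * slope} to \code{hi * slope}).
#' @examples
#' sensitivity(4.44e-3, 500, c(450, 550))$percent  # 10
#' @export
sensitivity <- function(slope, c_nominal, c_interval) {
  lo <- c_interval[1]
  hi <- c_interval[2]
  if (lo > c_nominal || hi < c_nominal) {
    stop_thermosar("interval must contain the nominal heat capacity",
                   "thermosar_validation_error")
  }
  list(percent = max(hi - c_nominal, c_nominal - lo) / c_nominal * 100,
       sar_range = c(low = lo * slope, high = hi * slope))
}

#' Thermal stabilization time
#'
#' Earliest time from which the absolute temperature-rise rate stays
#' strictly below a threshold over a continuous window (default
#' \code{|dT/dt| < 1e-4 K/s} over 10 min). Rates are forward differences
#' between consecutive samples at native sampling; a rate exactly at the
#' threshold does not satisfy the criterion.
#'
#' @param times sample times in s (strictly increasing).
#' @param delta_t temperature rise in K.
#' @param rate_threshold K/s (default \code{1e-4}).
#' @param window continuous interval length in s (default 600).
#' @return Stabilization time in s, or \code{NA} if never satisfied.
#' @export
stabilization_time <- function(times, delta_t, rate_threshold = 1e-4,
                               window = 600) {
  stopifnot(length(times) == length(delta_t), all(diff(times) > 0))
  if (max(times) - min(times) < window) {
    stop_thermosar("series shorter than the stabilization window",
                   "thermosar_domain_error")
  }
  rates <- diff(delta_t) / diff(times)
  starts <- times[-length(times)]
  ends <- times[-1]
  for (i in seq_along(starts)) {
    t0 <- starts[i]
    if (t0 + window > max(times) + 1e-9) break
    covered <- which(starts >= t0 - 1e-9 & ends <= t0 + window + 1e-9)
    if (length(covered) > 0 &&
        max(ends[covered]) >= t0 + window - 1e-9 &&
        all(abs(rates[covered]) < rate_threshold)) {
      return(t0)
    }
  }
  NA_real_
}

#' Conservative internal peak-to-surface temperature bound
#'
#' Infrared thermography only measures the surface rise \code{dTs}. For
#' uniform volumetric heating \code{rho SAReff} in a solid of thermal
#' conductivity \code{k} and characteristic half-thickness \code{L}, the
#' internal maximum exceeds the surface temperature by at most
#' \code{rho SAReff L^2 / (2 k)} (the steady slab closed form), giving a
#' peak-to-surface ratio bound
#' \code{RT <= 1 + rho SAReff L^2 / (2 k dTs)}. The excess scales
#' quadratically in \code{L}, linearly in \code{rho} and \code{SAReff}, and
#' inversely in \code{k}.
#'
#' @param material a \code{\link{material_thermal}} (uses \code{rho}, \code{k}).
#' @param sar_eff effective SAR in W/kg.
#' @param half_thickness characteristic half-thickness \code{L} in m
#'   (representative range for the phantom wall: 2.5--3 mm).
#' @param surface_rise measured surface temperature rise \code{dTs} in K, > 0.
#' @return An object of class \code{peak_surface_bound}: list with
#'   \code{excess_bound} (K), \code{ratio_RT}, plus the inputs.
#' @examples
#' peak_surface_bound(material_resin(), 0.8, 3e-3, 0.1)
#' @export
peak_surface_bound <- function(material, sar_eff, half_thickness,
                               surface_rise) {
  stopifnot(inherits(material, "material_thermal"))
  if (surface_rise <= 0) {
    stop_thermosar("surface_rise must be > 0 (ratio undefined otherwise)",
                   "thermosar_domain_error")
  }
  if (half_thickness <= 0) {
    stop_thermosar("half_thickness must be > 0", "thermosar_domain_error")
  }
  excess <- material$density_rho * sar_eff * half_thickness^2 /
    (2 * material$thermal_conductivity_k)
  structure(
    list(sar_eff = sar_eff, half_thickness_Lh = half_thickness,
         surface_rise_dTs = surface_rise, excess_bound = excess,
         ratio_RT = 1 + excess / surface_rise),
    class = "peak_surface_bound"
  )
}

#' @export
print.peak_surface_bound <- function(x, ...) {
  cat(sprintf(
    "Peak-to-surface bound: dTmax - dTs <= %.3f K, RT <= %.2f (L = %g mm)\n",
    x$excess_bound, x$ratio_RT, x$half_thickness_Lh * 1e3))
  invisible(x)
}
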