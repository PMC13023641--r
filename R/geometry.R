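#' Conical coil winding geometry
#'
#' Describes a uniformly wound conical helix: a copper winding following the
#' surface of a cone with half-angle \code{alpha} between the axis and the
#' generatrix, occupying the slant-coordinate interval \code{[s1, s2]} with
#' \code{n_turns} turns distributed uniformly along the slant length
#' \code{L = s2 - s1}. The azimuthal phase advances linearly with the slant
#' coordinate, \code{phi(s) = k s}, where \code{k = 2 pi N / L} is the
#' winding rate. The coil apex sits at the origin and the symmetry axis is
#' +z, so a point on the winding is
#' \code{(s sin(a) cos(ks), s sin(a) sin(ks), s cos(a))}.
#'
#' @param half_angle_alpha cone half-angle in radians, in (0, pi/2].
#' @param slant_lower_s1 lower slant bound in m, >= 0.
#' @param slant_upper_s2 upper slant bound in m, > \code{slant_lower_s1}.
#' @param n_turns_N number of turns, integer >= 1.
#' @param drive_current_I RMS drive current in A used for field computation.
#' @return An object of class \code{coil_geometry} with derived fields
#'   \code{slant_length_L} and \code{winding_rate_k}.
#' @examples
#' geo <- coil_geometry(pi / 4, 0.02, 0.12, 40, 0.75)
#' winding_rate(geo)
#' @export
coil_geometry <- function(half_angle_alpha, slant_lower_s1, slant_upper_s2,
                          n_turns_N, drive_current_I = 1) {
  if (!is.numeric(half_angle_alpha) || length(half_angle_alpha) != 1 ||
      !is.finite(half_angle_alpha) ||
      half_angle_alpha <= 0 || half_angle_alpha > pi / 2) {
    stop_thermosar("half_angle_alpha must be in (0, pi/2] radians",
                   "thermosar_validation_error")
  }
  if (slant_lower_s1 < 0 || slant_upper_s2 <= slant_lower_s1) {
    stop_thermosar("require 0 <= slant_lower_s1 < slant_upper_s2",
                   "thermosar_validation_error")
  }
  if (n_turns_N < 1 || n_turns_N != round(n_turns_N)) {
    stop_thermosar("n_turns_N must be a positive integer",
                   "thermosar_validation_error")
  }
  L <- slant_upper_s2 - slant_lower_s1
  structure(
    list(
      half_angle_alpha = half_angle_alpha,
      slant_lower_s1 = slant_lower_s1,
      slant_upper_s2 = slant_upper_s2,
      n_turns_N = as.integer(n_turns_N),
      drive_current_I = drive_current_I,
      slant_length_L = L,
      winding_rate_k = 2 * pi * n_turns_N / L
    ),
    class = "coil_geometry"
  )
}

#' @export
print.coil_geometry <- function(x, ...) {
  cat(sprintf(
    "Conical coil: alpha = %.4g deg, s in [%.4g, %.4g] m, N = %d, I = %.4g A\n",
    x$half_angle_alpha * 180 / pi, x$slant_lower_s1, x$slant_upper_s2,
    x$n_turns_N, x$drive_current_I))
  cat(sprintf("  slant length L = %.4g m, winding rate k = %.6g rad/m\n",
              x$slant_length_L, x$winding_rate_k))
  invisible(x)
}

#' Angular winding rate of the conical helix
#'
#' \code{k = 2 pi N / L}: azimuthal phase advance per unit slant length.
#'
#' @param geometry a \code{\link{coil_geometry}}.
#' @return Winding rate in rad/m.
#' @export
winding_rate <- function(geometry) {
  stopifnot(inherits(geometry, "coil_geometry"))
  geometry$winding_rate_k
}

#' Point on the conical helical winding
#'
#' Parametric representation of the winding at slant coordinate \code{s}:
#' \code{(s sin(a) cos(ks), s sin(a) sin(ks), s cos(a))}. The azimuthal
#' phase uses the absolute slant coordinate (\code{phi = k s}, not
#' \code{k (s - s1)}).
#'
#' @param geometry a \code{\link{coil_geometry}}.
#' @param s slant coordinate(s) in m; must lie within \code{[s1, s2]}.
#' @return A numeric matrix with one row per \code{s} and columns
#'   \code{x}, \code{y}, \code{z} (m); a single \code{s} returns a length-3
#'   named vector.
#' @export
helix_point <- function(geometry, s) {
  stopifnot(inherits(geometry, "coil_geometry"))
  if (any(s < geometry$slant_lower_s1 - 1e-15) ||
      any(s > geometry$slant_upper_s2 + 1e-15)) {
    stop_thermosar("slant coordinate s outside the winding range [s1, s2]",
                   "thermosar_domain_error")
  }
  a <- geometry$half_angle_alpha
  k <- geometry$winding_rate_k
  out <- cbind(x = s * sin(a) * cos(k * s),
               y = s * sin(a) * sin(k * s),
               z = s * cos(a))
  if (length(s) == 1) out[1, ] else out
}

#' PWM excitation waveform
#'
#' Square-wave pulsed drive described by repetition frequency, duty cycle
#' and RMS current. For an ideal unipolar square wave the peak current is
#' \code{rms / sqrt(duty)}; a bipolar square wave has peak equal to RMS.
#'
#' @param frequency_f repetition rate in Hz, > 0.
#' @param duty_D duty cycle fraction, in (0, 1).
#' @param rms_current RMS current in A, > 0.
#' @param rise_time optional rise time in s, >= 0.
#' @param polarity \code{"unipolar"} (default, single-ended low-side
#'   switching) or \code{"bipolar"}.
#' @return An object of class \code{excitation_waveform}.
#' @examples
#' wf <- excitation_waveform(10e3, 0.5, 0.75)
#' waveform_currents(wf)
#' @export
excitation_waveform <- function(frequency_f, duty_D, rms_current,
                                rise_time = 0,
                                polarity = c("unipolar", "bipolar")) {
  polarity <- match.arg(polarity)
  if (frequency_f <= 0) {
    stop_thermosar("frequency_f must be > 0", "thermosar_validation_error")
  }
  if (duty_D <= 0 || duty_D >= 1) {
    stop_thermosar("duty_D must be in (0, 1)", "thermosar_validation_error")
  }
  if (rms_current <= 0) {
    stop_thermosar("rms_current must be > 0", "thermosar_validation_error")
  }
  if (rise_time < 0) {
    stop_thermosar("rise_time must be >= 0", "thermosar_validation_error")
  }
  structure(
    list(frequency_f = frequency_f, duty_D = duty_D,
         rms_current = rms_current, rise_time = rise_time,
         polarity = polarity),
    class = "excitation_waveform"
  )
}

#' Peak and RMS currents of a square-wave excitation
#'
#' @param waveform an \code{\link{excitation_waveform}}.
#' @return Named numeric vector \code{c(peak_current, rms_current)} in A.
#' @export
waveform_currents <- function(waveform) {
  stopifnot(inherits(waveform, "excitation_waveform"))
  peak <- switch(waveform$polarity,
                 unipolar = waveform$rms_current / sqrt(waveform$duty_D),
                 bipolar = waveform$rms_current)
  c(peak_current = peak, rms_current = waveform$rms_current)
}

#' Idealized RL drive stage
#'
#' Supply voltage, coil inductance and total series resistance of the
#' switching stage, for the idealized exponential rise/decay transient of an
#' RL network.
#'
#' @param supply_voltage V, > 0.
#' @param inductance H, > 0.
#' @param series_resistance Ohm, > 0.
#' @return An object of class \code{rl_drive}.
#' @export
rl_drive <- function(supply_voltage, inductance, series_resistance) {
  if (supply_voltage <= 0 || inductance <= 0 || series_resistance <= 0) {
    stop_thermosar("all RL drive parameters must be strictly positive",
                   "thermosar_validation_error")
  }
  structure(
    list(supply_voltage = supply_voltage, inductance = inductance,
         series_resistance = series_resistance),
    class = "rl_drive"
  )
}

#' RL step-response current
#'
#' Rise branch \code{i(t) = (V/R) (1 - exp(-t R / L))}; decay branch
#' \code{i(t) = i0 exp(-t R / L)}.
#'
#' @param drive an \code{\link{rl_drive}}.
#' @param t time(s) in s, >= 0 (measured from the switching edge).
#' @param branch \code{"rise"} (default) or \code{"decay"}.
#' @param i0 initial current for the decay branch in A; defaults to the
#'   steady-state current \code{V/R}.
#' @return Current in A, same length as \code{t}.
#' @export
rl_step_current <- function(drive, t, branch = c("rise", "decay"),
                            i0 = NULL) {
  stopifnot(inherits(drive, "rl_drive"))
  branch <- match.arg(branch)
  if (any(t < 0)) {
    stop_thermosar("t must be >= 0", "thermosar_domain_error")
  }
  tau <- drive$inductance / drive$series_resistance
  i_inf <- drive$supply_voltage / drive$series_resistance
  if (branch == "rise") {
    i_inf * (1 - exp(-t / tau))
  } else {
    (i0 %||% i_inf) * exp(-t / tau)
  }
}
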