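#' Electrical and thermal properties of a medium
#'
#' @param density_rho mass density in kg/m^3, > 0.
#' @param heat_capacity_c specific heat capacity in J/(kg K), > 0.
#' @param thermal_conductivity_k thermal conductivity in W/(m K), > 0.
#' @param electrical_conductivity_sigma electrical conductivity in S/m, >= 0.
#' @param rel_permittivity_epsr relative permittivity (dimensionless).
#' @param rel_permeability_mur relative permeability (dimensionless).
#' @return An object of class \code{material_thermal}.
#' @export
material_thermal <- function(density_rho, heat_capacity_c,
                             thermal_conductivity_k,
                             electrical_conductivity_sigma = 0,
                             rel_permittivity_epsr = 1,
                             rel_permeability_mur = 1) {
  if (density_rho <= 0 || heat_capacity_c <= 0 || thermal_conductivity_k <= 0) {
    stop_thermosar("density, heat capacity and thermal conductivity must be > 0",
                   "thermosar_validation_error")
  }
  if (electrical_conductivity_sigma < 0) {
    stop_thermosar("electrical conductivity must be >= 0",
                   "thermosar_validation_error")
  }
  structure(
    list(density_rho = density_rho, heat_capacity_c = heat_capacity_c,
         thermal_conductivity_k = thermal_conductivity_k,
         electrical_conductivity_sigma = electrical_conductivity_sigma,
         rel_permittivity_epsr = rel_permittivity_epsr,
         rel_permeability_mur = rel_permeability_mur),
    class = "material_thermal"
  )
}

#' Material presets
#'
#' Bundled property sets for the media of the implanted-tibia exposure
#' scenario: MSLA photopolymer resin (tibia phantom), medical-grade
#' stainless steel (intramedullary implant) and a generic soft-tissue-like
#' medium. Resin: sigma ~ 1e-8 S/m, eps_r ~ 2.5, rho ~ 1150 kg/m^3,
#' c ~ 1300 J/(kg K), k ~ 0.25 W/(m K). Steel: sigma ~ 1.4e6 S/m,
#' mu_r ~ 1, rho ~ 7900 kg/m^3, c ~ 500 J/(kg K), k ~ 15 W/(m K).
#'
#' @return A \code{\link{material_thermal}}.
#' @name material_presets
NULL

#' @rdname material_presets
#' @export
material_resin <- function() {
  material_thermal(1150, 1300, 0.25,
                   electrical_conductivity_sigma = 1e-8,
                   rel_permittivity_epsr = 2.5)
}

#' @rdname material_presets
#' @export
material_steel <- function() {
  material_thermal(7900, 500, 15,
                   electrical_conductivity_sigma = 1.4e6,
                   rel_permeability_mur = 1)
}

#' @rdname material_presets
#' @export
material_tissue <- function() {
  # muscle-like soft tissue at low kHz frequencies
  material_thermal(1050, 3600, 0.5,
                   electrical_conductivity_sigma = 0.35,
                   rel_permittivity_epsr = 1e5)
}

#' Blood perfusion and metabolic source term
#'
#' The Pennes perfusion sink is \code{rho_b c_b omega_b (T_b - T)} with
#' \code{omega_b} in 1/s. Some sources quote perfusion as a volumetric mass
#' rate \code{w} in kg/(m^3 s), equivalent to \code{rho_b omega_b}; exactly
#' one of the two parameterizations must be supplied and the other is
#' derived.
#'
#' @param blood_density_rhob kg/m^3 (default 1050).
#' @param blood_heat_capacity_cb J/(kg K) (default 3617).
#' @param perfusion_rate_omegab 1/s, or \code{NULL}.
#' @param volumetric_mass_perfusion kg/(m^3 s), or \code{NULL}.
#' @param arterial_temp_Tb arterial blood temperature in K (or in the same
#'   temperature scale as the simulation).
#' @param metabolic_Qmet metabolic volumetric source in W/m^3 (default 0).
#' @return An object of class \code{perfusion_source}; field
#'   \code{active_form} records which parameterization was supplied.
#' @export
perfusion_source <- function(blood_density_rhob = 1050,
                             blood_heat_capacity_cb = 3617,
                             perfusion_rate_omegab = NULL,
                             volumetric_mass_perfusion = NULL,
                             arterial_temp_Tb = 310.15,
                             metabolic_Qmet = 0) {
  if (is.null(perfusion_rate_omegab) == is.null(volumetric_mass_perfusion)) {
    stop_thermosar(
      "supply exactly one of perfusion_rate_omegab or volumetric_mass_perfusion",
      "thermosar_validation_error")
  }
  if (is.null(perfusion_rate_omegab)) {
    active <- "volumetric_mass_perfusion"
    perfusion_rate_omegab <- volumetric_mass_perfusion / blood_density_rhob
  } else {
    active <- "perfusion_rate_omegab"
    volumetric_mass_perfusion <- perfusion_rate_omegab * blood_density_rhob
  }
  if (perfusion_rate_omegab < 0 || metabolic_Qmet < 0) {
    stop_thermosar("perfusion and metabolic rates must be nonnegative",
                   "thermosar_validation_error")
  }
  structure(
    list(blood_density_rhob = blood_density_rhob,
         blood_heat_capacity_cb = blood_heat_capacity_cb,
         perfusion_rate_omegab = perfusion_rate_omegab,
         volumetric_mass_perfusion = volumetric_mass_perfusion,
         arterial_temp_Tb = arterial_temp_Tb,
         metabolic_Qmet = metabolic_Qmet,
         active_form = active),
    class = "perfusion_source"
  )
}

#' One-dimensional thermal domain
#'
#' Symmetric 1-D slab (half-thickness) or solid cylinder (radius) with a
#' symmetry condition at the center (x = 0 or r = 0) and a configurable
#' condition at the outer surface.
#'
#' @param geometry_kind \code{"slab"} or \code{"cylinder"}.
#' @param half_thickness_or_radius extent in m, > 0.
#' @param node_count number of nodes (center to surface), >= 3.
#' @param boundary list: \code{list(type = "insulated")},
#'   \code{list(type = "fixed", T = )}, or
#'   \code{list(type = "convective", h = , T_ambient = )} with \code{h} in
#'   W/(m^2 K).
#' @return An object of class \code{thermal_domain_1d}.
#' @export
thermal_domain_1d <- function(geometry_kind = c("slab", "cylinder"),
                              half_thickness_or_radius, node_count,
                              boundary = list(type = "insulated")) {
  geometry_kind <- match.arg(geometry_kind)
  if (half_thickness_or_radius <= 0) {
    stop_thermosar("domain extent must be > 0", "thermosar_validation_error")
  }
  if (node_count < 3) {
    stop_thermosar("node_count must be >= 3", "thermosar_validation_error")
  }
  btype <- boundary$type %||% "insulated"
  if (!btype %in% c("insulated", "fixed", "convective")) {
    stop_thermosar("unknown boundary type", "thermosar_validation_error")
  }
  if (btype == "fixed" && is.null(boundary$T)) {
    stop_thermosar("fixed boundary requires T", "thermosar_validation_error")
  }
  if (btype == "convective" &&
      (is.null(boundary$h) || is.null(boundary$T_ambient))) {
    stop_thermosar("convective boundary requires h and T_ambient",
                   "thermosar_validation_error")
  }
  structure(
    list(geometry_kind = geometry_kind,
         extent = half_thickness_or_radius,
         node_count = as.integer(node_count),
         boundary = boundary),
    class = "thermal_domain_1d"
  )
}

#' Local specific absorption rate
#'
#' \code{SAR = sigma Erms^2 / rho}: absorbed electromagnetic power per unit
#' mass from the RMS induced electric field.
#'
#' @param material a \code{\link{material_thermal}}.
#' @param erms RMS electric field in V/m, >= 0.
#' @return SAR in W/kg.
#' @export
local_sar <- function(material, erms) {
  stopifnot(inherits(material, "material_thermal"))
  if (any(erms < 0)) {
    stop_thermosar("erms must be >= 0", "thermosar_domain_error")
  }
  material$electrical_conductivity_sigma * erms^2 / material$density_rho
}

#' Volumetric heat source from SAR
#'
#' \code{Q_ext = rho SAR}: the external source term of the bioheat equation.
#'
#' @param material a \code{\link{material_thermal}}.
#' @param sar SAR in W/kg, >= 0.
#' @return Volumetric source in W/m^3.
#' @export
sar_to_volumetric <- function(material, sar) {
  stopifnot(inherits(material, "material_thermal"))
  if (any(sar < 0)) {
    stop_thermosar("sar must be >= 0", "thermosar_domain_error")
  }
  material$density_rho * sar
}

# ---- finite-volume discretization -----------------------------------------

# Build the conservative node-centered discretization:
#   Cvol_i dT_i/dt = sum_j G_ij (T_j - T_i) + boundary exchange + S_i
# Returns list(x, cvol = rho c * cell volume, g_low/g_up = face conductances,
# loss = diagonal loss coefficient (perfusion + convective), rhs = constant
# source per node in W, fixed = index of Dirichlet node or NA).
.discretize_1d <- function(domain, material, perfusion, q_ext) {
  n <- domain$node_count
  Lh <- domain$extent
  h <- Lh / (n - 1)
  x <- seq(0, Lh, length.out = n)
  k <- material$thermal_conductivity_k
  rc <- material$density_rho * material$heat_capacity_c
  if (length(q_ext) == 1) q_ext <- rep(q_ext, n)
  if (length(q_ext) != n) {
    stop_thermosar("q_ext must be scalar or one value per node",
                   "thermosar_validation_error")
  }
  if (domain$geometry_kind == "slab") {
    # per unit face area
    vol <- c(h / 2, rep(h, n - 2), h / 2)
    area_face <- rep(1, n - 1)           # faces between i and i+1
    area_out <- 1
  } else {
    rf <- pmin(pmax(x + h / 2, 0), Lh)   # outer face radius per cell
    rin <- pmax(x - h / 2, 0)
    vol <- pi * (rf^2 - rin^2)           # per unit length
    area_face <- 2 * pi * (x[-n] + h / 2)
    area_out <- 2 * pi * Lh
  }
  g <- k * area_face / h                 # conductance across each face
  cvol <- rc * vol
  loss <- rep(0, n)
  rhs <- q_ext * vol
  if (!is.null(perfusion)) {
    pc <- perfusion$blood_density_rhob * perfusion$blood_heat_capacity_cb *
      perfusion$perfusion_rate_omegab
    loss <- loss + pc * vol
    rhs <- rhs + (pc * perfusion$arterial_temp_Tb +
                    perfusion$metabolic_Qmet) * vol
  }
  fixed <- NA_integer_
  btype <- domain$boundary$type %||% "insulated"
  if (btype == "convective") {
    hc <- domain$boundary$h
    loss[n] <- loss[n] + hc * area_out
    rhs[n] <- rhs[n] + hc * area_out * domain$boundary$T_ambient
  } else if (btype == "fixed") {
    fixed <- n
  }
  list(x = x, h = h, cvol = cvol, g = g, loss = loss, rhs = rhs,
       fixed = fixed, vol = vol)
}

# Thomas algorithm for tridiagonal systems: sub a (n-1), diag b (n),
# super c (n-1), rhs d (n)
.thomas <- function(a, b, c, d) {
  n <- length(b)
  cp <- numeric(n - 1)
  dp <- numeric(n)
  cp[1] <- c[1] / b[1]
  dp[1] <- d[1] / b[1]
  for (i in 2:n) {
    m <- b[i] - a[i - 1] * cp[i - 1]
    if (i < n) cp[i] <- c[i] / m
    dp[i] <- (d[i] - a[i - 1] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Transient 1-D bioheat solution
#'
#' Solves the Pennes bioheat equation
#' \code{rho c dT/dt = div(k grad T) + rho_b c_b omega_b (T_b - T) + Q_met +
#' Q_ext} on a symmetric slab or cylinder, by a conservative node-centered
#' finite-volume scheme (second-order in space). The implicit
#' (backward-Euler, unconditionally stable) scheme is the default; the
#' explicit scheme errors if \code{dt} exceeds its stability bound, naming
#' the maximum stable step.
#'
#' @param domain a \code{\link{thermal_domain_1d}}.
#' @param material a \code{\link{material_thermal}}.
#' @param perfusion a \code{\link{perfusion_source}} or \code{NULL} (the
#'   reduced, perfusion-free form).
#' @param q_ext volumetric source in W/m^3: scalar or per-node vector
#'   (typically \code{\link{sar_to_volumetric}} output).
#' @param t_end simulation end time in s.
#' @param dt time step in s.
#' @param scheme \code{"implicit"} (default) or \code{"explicit"}.
#' @param t_init initial uniform temperature (K or deg C; any consistent
#'   scale). Default 0, i.e. temperatures are rises over ambient.
#' @param snapshot_every store every m-th step (default 1).
#' @return An object of class \code{temperature_field}: list with
#'   \code{x} (node positions, m), \code{times} (s), \code{T} (time x node
#'   matrix), and \code{energy_residual} (relative mismatch of the global
#'   energy balance over the run; exact bookkeeping for insulated domains).
#' @export
solve_transient <- function(domain, material, perfusion = NULL, q_ext,
                            t_end, dt, scheme = c("implicit", "explicit"),
                            t_init = 0, snapshot_every = 1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(domain, "thermal_domain_1d"),
            inherits(material, "material_thermal"))
  d <- .discretize_1d(domain, material, perfusion, q_ext)
  n <- length(d$x)
  n_steps <- ceiling(t_end / dt - 1e-9)
  # rate-matrix diagonal magnitude for the explicit stability bound
  diag_rate <- (c(d$g, 0) + c(0, d$g) + d$loss) / d$cvol
  if (scheme == "explicit") {
    dt_max <- 1 / max(diag_rate)
    if (dt > dt_max) {
      stop_thermosar(
        sprintf("explicit step dt = %g s unstable; maximum stable dt = %g s",
                dt, dt_max),
        "thermosar_stability_error")
    }
  }
  T_now <- rep(t_init, n)
  if (!is.na(d$fixed)) T_now[d$fixed] <- domain$boundary$T
  keep <- unique(c(seq(0, n_steps, by = snapshot_every), n_steps))
  Tout <- matrix(NA_real_, length(keep), n)
  times <- keep * dt
  Tout[1, ] <- T_now
  row <- 1
  # assemble implicit tridiagonal system (I*C/dt + G + loss)
  lower <- -c(d$g)
  upper <- -c(d$g)
  diag_A <- d$cvol / dt + c(d$g, 0) + c(0, d$g) + d$loss
  if (!is.na(d$fixed)) {
    i <- d$fixed
    diag_A[i] <- 1
    if (i > 1) lower[i - 1] <- 0
    if (i < n) upper[i] <- 0
  }
  absorbed <- 0
  for (step in seq_len(n_steps)) {
    if (scheme == "implicit") {
      rhs <- d$cvol / dt * T_now + d$rhs
      if (!is.na(d$fixed)) rhs[d$fixed] <- domain$boundary$T
      T_new <- .thomas(lower, diag_A, upper, rhs)
    } else {
      flux <- c(d$g * diff(T_now), 0) - c(0, d$g * diff(T_now))
      # flux[i] = net conductive inflow into cell i
      dTdt <- (flux + d$rhs - d$loss * T_now) / d$cvol
      T_new <- T_now + dt * dTdt
      if (!is.na(d$fixed)) T_new[d$fixed] <- domain$boundary$T
    }
    absorbed <- absorbed + sum(d$rhs - d$loss * T_new) * dt
    T_now <- T_new
    if (step %in% keep) {
      row <- row + 1
      Tout[row, ] <- T_now
    }
  }
  # global energy balance (meaningful for insulated domains: stored internal
  # energy change vs time-integrated net source)
  stored <- sum(d$cvol * (T_now - Tout[1, ]))
  resid <- if (abs(absorbed) > 0) abs(stored - absorbed) / abs(absorbed) else 0
  structure(
    list(x = d$x, times = times, T = Tout, energy_residual = resid,
         scheme = scheme, domain = domain),
    class = "temperature_field"
  )
}

#' Steady-state 1-D bioheat solution
#'
#' Direct linear solve of the discretized steady equation (the
#' infinite-time limit of \code{\link{solve_transient}}). Requires a
#' temperature-anchoring mechanism (fixed or convective boundary, or
#' perfusion); a purely insulated sourced domain has no steady state.
#'
#' @inheritParams solve_transient
#' @return List with \code{x} and steady \code{T} per node.
#' @export
steady_state <- function(domain, material, perfusion = NULL, q_ext) {
  d <- .discretize_1d(domain, material, perfusion, q_ext)
  n <- length(d$x)
  lower <- -c(d$g)
  upper <- -c(d$g)
  diag_A <- c(d$g, 0) + c(0, d$g) + d$loss
  rhs <- d$rhs
  if (!is.na(d$fixed)) {
    i <- d$fixed
    diag_A[i] <- 1
    if (i > 1) lower[i - 1] <- 0
    if (i < n) upper[i] <- 0
    rhs[i] <- domain$boundary$T
  }
  if (all(d$loss == 0) && is.na(d$fixed) && any(d$rhs != 0)) {
    stop_thermosar("insulated sourced domain has no steady state",
                   "thermosar_validation_error")
  }
  list(x = d$x, T = .thomas(lower, diag_A, upper, rhs))
}

#' Lumped-capacitance thermal response
#'
#' Zero-dimensional heat balance \code{m c dT/dt = P_abs - hA (T - T_amb)}.
#' With \code{loss_hA = 0} this is the early-time lumped limit
#' (\code{m c dT/dt ~ P_abs}, a linear rise of slope \code{P/(m c)}); with
#' a Newton-cooling loss it plateaus at \code{dT = P/hA}.
#'
#' @param mass_m mass in kg, > 0.
#' @param heat_capacity_c specific heat capacity in J/(kg K), > 0.
#' @param p_abs absorbed power: scalar in W, or a function of time
#'   \code{P(t)} in W.
#' @param loss_hA loss conductance in W/K, >= 0.
#' @param t_ambient ambient temperature (only shifts the absolute scale;
#'   output is the rise over ambient).
#' @param t_end end time in s.
#' @param times optional explicit output times (s); default 601 equispaced
#'   points on \code{[0, t_end]}.
#' @return Data frame with columns \code{time} (s) and \code{delta_t} (K),
#'   the temperature rise over ambient.
#' @export
solve_lumped <- function(mass_m, heat_capacity_c, p_abs, loss_hA = 0,
                         t_ambient = 0, t_end, times = NULL) {
  if (mass_m <= 0 || heat_capacity_c <= 0) {
    stop_thermosar("mass and heat capacity must be > 0",
                   "thermosar_validation_error")
  }
  if (loss_hA < 0) {
    stop_thermosar("loss_hA must be >= 0", "thermosar_validation_error")
  }
  if (is.null(times)) times <- seq(0, t_end, length.out = 601)
  mc <- mass_m * heat_capacity_c
  if (is.function(p_abs)) {
    out <- deSolve::ode(
      y = c(dT = 0), times = times,
      func = function(t, y, parms) {
        list((p_abs(t) - loss_hA * y[1]) / mc)
      }, parms = NULL, method = "lsoda")
    delta_t <- out[, "dT"]
  } else if (loss_hA == 0) {
    delta_t <- p_abs * times / mc
  } else {
    tau <- mc / loss_hA
    delta_t <- (p_abs / loss_hA) * (1 - exp(-times / tau))
  }
  data.frame(time = times, delta_t = delta_t)
}

#' Calibrate a lumped first-order response to a measured series
#'
#' Fits the first-order curve \code{dT(t) = A (1 - exp(-t / tau))} to a
#' measured temperature-rise series and converts \code{(A, tau)} into the
#' lumped parameters \code{P_abs = m c A / tau} and \code{hA = m c / tau}.
#' \code{method = "ls"} fits both parameters by nonlinear least squares;
#' \code{method = "anchor"} instead takes a prescribed initial slope and
#' plateau (\code{A = plateau}, \code{tau = plateau / slope}).
#'
#' @param times,delta_t measured series (s, K); ignored for
#'   \code{method = "anchor"}.
#' @param mass_m,heat_capacity_c lumped body parameters (kg, J/(kg K)).
#' @param method \code{"ls"} or \code{"anchor"}.
#' @param slope,plateau anchor values (K/s, K) for \code{method = "anchor"};
#'   also used as the starting point of the least-squares fit when given.
#' @return List with \code{p_abs} (W), \code{loss_hA} (W/K), \code{plateau}
#'   (K), \code{tau} (s) and \code{curve(t)}, the fitted response function.
#' @export
calibrate_lumped <- function(times = NULL, delta_t = NULL, mass_m,
                             heat_capacity_c, method = c("ls", "anchor"),
                             slope = NULL, plateau = NULL) {
  method <- match.arg(method)
  mc <- mass_m * heat_capacity_c
  if (method == "anchor") {
    if (is.null(slope) || is.null(plateau)) {
      stop_thermosar("anchor calibration needs slope and plateau",
                     "thermosar_validation_error")
    }
    A <- plateau
    tau <- plateau / slope
  } else {
    stopifnot(!is.null(times), !is.null(delta_t))
    A0 <- plateau %||% max(delta_t)
    tau0 <- if (!is.null(slope)) A0 / slope else max(times) / 5
    fit <- stats::nls(delta_t ~ A * (1 - exp(-times / tau)),
                      start = list(A = A0, tau = tau0))
    A <- stats::coef(fit)[["A"]]
    tau <- stats::coef(fit)[["tau"]]
  }
  list(p_abs = mc * A / tau, loss_hA = mc / tau, plateau = A, tau = tau,
       curve = function(t) A * (1 - exp(-t / tau)))
}

# ---- eddy-current loss -----------------------------------------------------

#' Mean-square rate of change of a flux-density waveform
#'
#' Supported waveform descriptions (lists):
#' \itemize{
#'   \item \code{list(type = "sine", b0, freq)}: closed form
#'     \code{omega^2 b0^2 / 2};
#'   \item \code{list(type = "trapezoid", b0, freq, duty, rise_frac)}:
#'     unipolar trapezoid with rise/fall time \code{rise_frac / freq};
#'     closed form \code{2 b0^2 / (t_rise T)};
#'   \item \code{list(type = "square", b0, freq, duty, n_harmonics)}:
#'     harmonic truncation of the ideal square wave (default 15 odd
#'     harmonics) -- an ideal square wave has unbounded dB/dt, so a finite
#'     band limit is mandatory;
#'   \item \code{list(type = "samples", t, b, freq)}: one period of samples,
#'     differentiated numerically.
#' }
#'
#' @param waveform waveform description list (see Details).
#' @param method \code{"analytic"} (closed form / spectral as appropriate),
#'   \code{"time"} (dense sampling + numerical derivative) or
#'   \code{"spectral"} (Fourier sum over harmonics).
#' @param n_samples samples per period for the numerical paths
#'   (default 8192).
#' @param n_harmonics harmonic cut-off for the spectral path (default: all
#'   below Nyquist; for \code{type = "square"} the waveform's own
#'   \code{n_harmonics}, default 15 odd harmonics).
#' @return Mean of \code{(dB/dt)^2} over one period, in T^2/s^2.
#' @export
mean_square_dbdt <- function(waveform,
                             method = c("analytic", "time", "spectral"),
                             n_samples = 8192, n_harmonics = NULL) {
  method <- match.arg(method)
  type <- waveform$type %||% "samples"
  if (type == "square" && method != "spectral") {
    # ideal square has unbounded dB/dt; only the band-limited form is defined
    method <- "spectral"
  }
  if (method == "analytic") {
    if (type == "sine") {
      w <- 2 * pi * waveform$freq
      return(w^2 * waveform$b0^2 / 2)
    }
    if (type == "trapezoid") {
      per <- 1 / waveform$freq
      tr <- (waveform$rise_frac %||% 0.01) * per
      return(2 * waveform$b0^2 / (tr * per))
    }
    method <- "time"  # samples: fall through to the numeric path
  }
  samp <- .sample_waveform(waveform, n_samples)
  if (method == "time") {
    dt <- samp$t[2] - samp$t[1]
    # periodic central differences
    bp <- c(samp$b[-1], samp$b[1])
    bm <- c(samp$b[length(samp$b)], samp$b[-length(samp$b)])
    dbdt <- (bp - bm) / (2 * dt)
    return(mean(dbdt^2))
  }
  # spectral: Parseval sum over harmonics of the derivative
  N <- length(samp$b)
  f0 <- waveform$freq %||% (1 / (N * (samp$t[2] - samp$t[1])))
  cn <- stats::fft(samp$b) / N
  freqs <- c(0:(floor(N / 2)), -((ceiling(N / 2) - 1):1)) * f0
  if (type == "square") {
    n_harmonics <- n_harmonics %||% waveform$n_harmonics %||% 29
  }
  if (!is.null(n_harmonics)) {
    cn[abs(freqs) > n_harmonics * f0 + 1e-9] <- 0
  }
  sum((2 * pi * freqs)^2 * Mod(cn)^2)
}

# sample one period of a waveform description
.sample_waveform <- function(waveform, n_samples) {
  type <- waveform$type %||% "samples"
  if (type == "samples") {
    return(list(t = waveform$t, b = waveform$b))
  }
  per <- 1 / waveform$freq
  t <- seq(0, per, length.out = n_samples + 1)[-(n_samples + 1)]
  b <- switch(type,
    sine = waveform$b0 * sin(2 * pi * waveform$freq * t),
    square = ,
    trapezoid = {
      duty <- waveform$duty %||% 0.5
      tr <- (waveform$rise_frac %||% 0.01) * per
      if (type == "square") tr <- 0
      th <- duty * per
      up <- pmin(1, t / max(tr, per * 1e-9))
      down <- pmin(1, pmax(0, (t - th) / max(tr, per * 1e-9)))
      waveform$b0 * pmax(0, up - down)
    },
    stop_thermosar("unknown waveform type", "thermosar_validation_error"))
  list(t = t, b = b)
}

#' Band-limit a waveform to its first harmonics
#'
#' Reconstructs the waveform from its Fourier components up to
#' \code{n_harmonics} times the fundamental, returning a samples-type
#' waveform. Useful to compare spectral and time-domain loss computations on
#' an identical band-limited signal.
#'
#' @param waveform waveform description (see \code{\link{mean_square_dbdt}}).
#' @param n_harmonics harmonic cut-off.
#' @param n_samples samples per period (default 8192).
#' @return A samples-type waveform list.
#' @export
bandlimit_waveform <- function(waveform, n_harmonics, n_samples = 8192) {
  samp <- .sample_waveform(waveform, n_samples)
  N <- length(samp$b)
  cn <- stats::fft(samp$b)
  freqs <- c(0:(floor(N / 2)), -((ceiling(N / 2) - 1):1))
  cn[abs(freqs) > n_harmonics] <- 0
  list(type = "samples", t = samp$t, b = Re(stats::fft(cn, inverse = TRUE)) / N,
       freq = waveform$freq)
}

#' Eddy-current loss in a conducting cylinder under an axial field
#'
#' Quasi-static model of a solid conducting cylinder (radius \code{a}) in a
#' spatially uniform axial flux density \code{B(t)}: the induced azimuthal
#' electric field is \code{E = -(r/2) dB/dt}, giving a cross-section-averaged
#' volumetric Joule loss \code{sigma a^2 <(dB/dt)^2> / 8}. Validity requires
#' the skin depth to exceed the radius; otherwise the result carries a
#' warning flag (the unshielded model then underestimates nothing but its
#' own assumptions -- induced-field shielding makes it an overestimate of
#' the interior field and the loss model an approximation).
#'
#' @param implant_radius cylinder radius in m.
#' @param implant_length cylinder length in m.
#' @param sigma electrical conductivity in S/m.
#' @param b_waveform axial flux-density waveform description
#'   (see \code{\link{mean_square_dbdt}}).
#' @param density_rho implant density in kg/m^3 (default 7900, stainless
#'   steel).
#' @param mu_r relative permeability (default 1).
#' @param msq_method method forwarded to \code{\link{mean_square_dbdt}}.
#' @return List with \code{p_abs} (W), \code{sar_implant} (W/kg),
#'   \code{volumetric_loss} (W/m^3), \code{skin_depth} (m at the
#'   fundamental) and \code{quasi_static_ok} (logical flag).
#' @export
eddy_loss <- function(implant_radius, implant_length, sigma, b_waveform,
                      density_rho = 7900, mu_r = 1,
                      msq_method = "analytic") {
  msq <- mean_square_dbdt(b_waveform, method = msq_method)
  vol_loss <- sigma * implant_radius^2 * msq / 8
  volume <- pi * implant_radius^2 * implant_length
  p_abs <- vol_loss * volume
  f0 <- b_waveform$freq %||% NA_real_
  skin <- if (is.finite(f0) && sigma > 0) {
    sqrt(2 / (2 * pi * f0 * MU0 * mu_r * sigma))
  } else {
    Inf
  }
  ok <- skin >= implant_radius
  if (!ok) {
    warning("skin depth (", signif(skin, 3),
            " m) below implant radius; quasi-static loss model inaccurate")
  }
  list(p_abs = p_abs, sar_implant = vol_loss / density_rho,
       volumetric_loss = vol_loss, skin_depth = skin, quasi_static_ok = ok)
}
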