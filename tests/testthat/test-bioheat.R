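test_that("local SAR and volumetric source follow the defining relations", {
  m <- material_thermal(1000, 4000, 0.5, electrical_conductivity_sigma = 0.5)
  expect_equal(local_sar(m, 10), 0.05)
  expect_equal(local_sar(m, 0), 0)
  # round trip: rho * (sigma E^2 / rho) = sigma E^2
  expect_equal(sar_to_volumetric(m, local_sar(m, 10)), 0.5 * 100)

  expect_equal(sar_to_volumetric(m, 2), 2000)
  expect_equal(sar_to_volumetric(m, 0), 0)
  # printed resin density x printed resin SAReff
  expect_equal(sar_to_volumetric(material_resin(), 0.8), 920)
})

test_that("insulated uniform-source transient rises as q t / (rho c)", {
  m <- material_resin()
  dom <- thermal_domain_1d("slab", 3e-3, 41)
  tf <- solve_transient(dom, m, NULL, q_ext = 920, t_end = 120, dt = 2)
  expected <- 920 * tf$times / (m$density_rho * m$heat_capacity_c)
  for (i in seq_along(tf$times)) {
    expect_equal(tf$T[i, ], rep(expected[i], 41), tolerance = 1e-9)
  }
  expect_lt(tf$energy_residual, 1e-3)

  # cylinder geometry conserves energy too
  domc <- thermal_domain_1d("cylinder", 3e-3, 41)
  tfc <- solve_transient(domc, m, NULL, q_ext = 920, t_end = 120, dt = 2)
  expect_equal(tfc$T[nrow(tfc$T), ], rep(expected[length(expected)], 41),
               tolerance = 1e-9)
  expect_lt(tfc$energy_residual, 1e-3)
})

test_that("steady slab with fixed surfaces matches the parabolic closed form", {
  m <- material_resin()
  Lh <- 3e-3
  q <- 920
  dom <- thermal_domain_1d("slab", Lh, 200, boundary = list(type = "fixed",
                                                            T = 0))
  ss <- steady_state(dom, m, NULL, q_ext = q)
  closed <- q * Lh^2 / (2 * m$thermal_conductivity_k)
  expect_equal(ss$T[1] - ss$T[200], closed, tolerance = 5e-3)
  # full profile is parabolic: T(x) = q (L^2 - x^2) / (2k)
  expect_equal(ss$T, q * (Lh^2 - ss$x^2) / (2 * m$thermal_conductivity_k),
               tolerance = 1e-6)
})

test_that("steady profiles are exact for parabolas and converge for cosh", {
  # the conservative FV scheme reproduces polynomial steady profiles to
  # round-off in both geometries (uniform source, linear flux)
  m <- material_resin()
  Lh <- 3e-3
  q <- 920
  dom_s <- thermal_domain_1d("slab", Lh, 11,
                             boundary = list(type = "fixed", T = 0))
  expect_lt(abs(steady_state(dom_s, m, NULL, q)$T[1] -
                  q * Lh^2 / (2 * m$thermal_conductivity_k)), 1e-12)
  dom_c <- thermal_domain_1d("cylinder", Lh, 11,
                             boundary = list(type = "fixed", T = 0))
  expect_lt(abs(steady_state(dom_c, m, NULL, q)$T[1] -
                  q * Lh^2 / (4 * m$thermal_conductivity_k)), 1e-12)

  # with a perfusion sink the solution is a cosh profile, which the scheme
  # does not represent exactly: the center error must shrink at second order
  mt <- material_tissue()
  L <- 0.01
  perf <- perfusion_source(perfusion_rate_omegab = 5e-4,
                           arterial_temp_Tb = 0)
  beta <- perf$blood_density_rhob * perf$blood_heat_capacity_cb * 5e-4
  mu <- sqrt(beta / mt$thermal_conductivity_k)
  exact0 <- (q / beta) * (1 - 1 / cosh(mu * L))
  err <- sapply(c(6, 11, 21, 41), function(n) {
    dom <- thermal_domain_1d("slab", L, n,
                             boundary = list(type = "fixed", T = 0))
    abs(steady_state(dom, mt, perf, q_ext = q)$T[1] - exact0)
  })
  # halving h should cut the error by about 4; allow slack for the
  # node-centered boundary treatment
  expect_gt(err[1] / err[2], 2)
  expect_gt(err[2] / err[3], 2)
  expect_gt(err[3] / err[4], 2)
})

test_that("perfusion acts as an exponential sink toward arterial temperature", {
  m <- material_tissue()
  perf <- perfusion_source(perfusion_rate_omegab = 5e-4,
                           arterial_temp_Tb = 0)
  dom <- thermal_domain_1d("slab", 0.01, 21)
  tf <- solve_transient(dom, m, perf, q_ext = 0, t_end = 400, dt = 0.5,
                        t_init = 1)
  rate <- perf$blood_density_rhob * perf$blood_heat_capacity_cb * 5e-4 /
    (m$density_rho * m$heat_capacity_c)
  expect_equal(tf$T[nrow(tf$T), ], rep(exp(-rate * 400), 21),
               tolerance = 2e-3)
})

test_that("steady temperature decreases monotonically with perfusion rate", {
  m <- material_tissue()
  dom <- thermal_domain_1d("slab", 0.01, 31)
  steadies <- sapply(c(1e-4, 5e-4, 2e-3), function(wb) {
    perf <- perfusion_source(perfusion_rate_omegab = wb,
                             arterial_temp_Tb = 0)
    max(steady_state(dom, m, perf, q_ext = 500)$T)
  })
  expect_true(all(diff(steadies) < 0))
})

test_that("both perfusion parameterizations agree after conversion", {
  p1 <- perfusion_source(perfusion_rate_omegab = 5e-4)
  p2 <- perfusion_source(volumetric_mass_perfusion = 5e-4 * 1050)
  expect_equal(p1$volumetric_mass_perfusion, p2$volumetric_mass_perfusion)
  expect_equal(p2$perfusion_rate_omegab, 5e-4)
  expect_equal(p2$active_form, "volumetric_mass_perfusion")
  expect_error(perfusion_source(perfusion_rate_omegab = 1e-4,
                                volumetric_mass_perfusion = 0.5),
               class = "thermosar_validation_error")
})

test_that("explicit scheme rejects unstable steps, naming the bound", {
  m <- material_resin()
  dom <- thermal_domain_1d("slab", 3e-3, 41)
  err <- tryCatch(
    solve_transient(dom, m, NULL, 0, t_end = 10, dt = 10,
                    scheme = "explicit"),
    error = function(e) e)
  expect_s3_class(err, "thermosar_stability_error")
  expect_match(conditionMessage(err), "maximum stable dt")
  dt_max <- as.numeric(sub(".*maximum stable dt = ([0-9.e-]+) s.*", "\\1",
                           conditionMessage(err)))
  # a step just under the bound runs, and matches the implicit solution
  tf_e <- solve_transient(dom, m, NULL, 920, t_end = 50, dt = dt_max * 0.9,
                          scheme = "explicit")
  expect_equal(tf_e$T[nrow(tf_e$T), 1],
               920 * 50 / (m$density_rho * m$heat_capacity_c),
               tolerance = 1e-2)
})

test_that("high-conductivity slab converges to the lumped solution", {
  # Biot number -> 0: the convectively cooled slab behaves as a lumped body
  m <- material_resin()
  mk <- material_thermal(m$density_rho, m$heat_capacity_c,
                         100 * m$thermal_conductivity_k)
  Lh <- 3e-3
  h <- 10
  dom <- thermal_domain_1d("slab", Lh, 41,
                           boundary = list(type = "convective", h = h,
                                           T_ambient = 0))
  q <- 5e4
  tf <- solve_transient(dom, mk, NULL, q, t_end = 600, dt = 0.25)
  # per unit area: m c = rho c Lh, P = q Lh, hA = h
  lump <- solve_lumped(mass_m = m$density_rho * Lh,
                       heat_capacity_c = m$heat_capacity_c,
                       p_abs = q * Lh, loss_hA = h, t_end = 600,
                       times = tf$times)
  expect_lt(max(abs(tf$T[, 1] - lump$delta_t)) / max(lump$delta_t), 0.01)
})

test_that("lumped solution has the closed-form slope and plateau", {
  out <- solve_lumped(0.1, 500, p_abs = 0.222, loss_hA = 0, t_end = 100)
  expect_equal(out$delta_t, 0.222 * out$time / 50, tolerance = 1e-12)

  out2 <- solve_lumped(0.1, 500, p_abs = 0.222, loss_hA = 0.4933,
                       t_end = 5000)
  expect_equal(out2$delta_t[nrow(out2)], 0.222 / 0.4933, tolerance = 1e-6)

  # a time-varying drive through the ODE path agrees with the constant-power
  # closed form when the function is constant
  out3 <- solve_lumped(0.1, 500, p_abs = function(t) 0.222, loss_hA = 0.4933,
                       t_end = 500, times = seq(0, 500, 50))
  expect_equal(out3$delta_t,
               (0.222 / 0.4933) * (1 - exp(-0.4933 * out3$time / 50)),
               tolerance = 1e-5)
})

test_that("lumped calibration reproduces the measured implant series", {
  rs <- reference_series("0.75A")
  # least-squares fit passes within 0.05 K of every tabulated mean
  cal <- calibrate_lumped(rs$time_s, rs$implant_mean, mass_m = 0.1,
                          heat_capacity_c = 500, method = "ls")
  expect_lt(max(abs(cal$curve(rs$time_s) - rs$implant_mean)), 0.05)

  # the slope/plateau-anchored curve tracks the series within the camera
  # resolution but not within 0.05 K everywhere (documented discrepancy)
  anch <- calibrate_lumped(mass_m = 0.1, heat_capacity_c = 500,
                           method = "anchor", slope = 4.44e-3,
                           plateau = 0.45)
  dev <- abs(anch$curve(rs$time_s) - rs$implant_mean)
  expect_lt(max(dev), 0.1)
  expect_gt(max(dev), 0.05)
  # anchor bookkeeping: initial slope and plateau are reproduced exactly
  expect_equal(anch$p_abs / (0.1 * 500), 4.44e-3)
  expect_equal(anch$p_abs / anch$loss_hA, 0.45)
})

test_that("eddy loss reproduces closed forms and the time-domain oracle", {
  # no field variation, no loss (10 kHz in steel violates the skin-depth
  # assumption, which is flagged but does not affect the zero result)
  expect_warning(
    z <- eddy_loss(5e-3, 0.1, 1.4e6,
                   list(type = "samples", t = seq(0, 1e-4, length.out = 64),
                        b = rep(1e-4, 64), freq = 1e4)),
    "skin depth")
  expect_equal(z$p_abs, 0)

  # sinusoid closed form: volumetric loss = sigma a^2 w^2 B0^2 / 16
  w <- 2 * pi * 1e3
  el <- eddy_loss(5e-3, 0.1, 1e5, list(type = "sine", b0 = 2e-4, freq = 1e3),
                  density_rho = 7900)
  expect_equal(el$volumetric_loss, 1e5 * (5e-3)^2 * w^2 * (2e-4)^2 / 16,
               tolerance = 1e-12)
  expect_equal(el$sar_implant, el$volumetric_loss / 7900)
  expect_equal(el$p_abs, el$volumetric_loss * pi * (5e-3)^2 * 0.1)
  expect_true(el$quasi_static_ok)

  # band-limited trapezoid: spectral sum equals time-domain integration
  bl <- bandlimit_waveform(list(type = "trapezoid", b0 = 2e-4, freq = 1e4,
                                duty = 0.5, rise_frac = 0.05),
                           n_harmonics = 60)
  m_time <- mean_square_dbdt(bl, method = "time")
  m_spec <- mean_square_dbdt(bl, method = "spectral")
  expect_lt(abs(m_time - m_spec) / m_spec, 5e-3)

  # analytic trapezoid mean square: 2 b0^2 / (t_rise T)
  tz <- list(type = "trapezoid", b0 = 2e-4, freq = 1e4, duty = 0.5,
             rise_frac = 0.05)
  expect_equal(mean_square_dbdt(tz, method = "analytic"),
               2 * (2e-4)^2 / ((0.05 / 1e4) * 1e-4), tolerance = 1e-12)
  expect_equal(mean_square_dbdt(tz, method = "time"),
               mean_square_dbdt(tz, method = "analytic"), tolerance = 5e-3)

  # skin-depth violation raises the quasi-static flag
  expect_warning(
    deep <- eddy_loss(5e-3, 0.1, 1.4e6,
                      list(type = "sine", b0 = 2e-4, freq = 1e4)),
    "skin depth")
  expect_false(deep$quasi_static_ok)
})
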