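# shared fixtures for the test suite

# documented default coil fixture (alpha 45 deg, s in [0.02, 0.12] m, N = 40)
fix_geo <- function(current = 0.75) {
  coil_geometry(pi / 4, 0.02, 0.12, 40, current)
}

# independent cross-product oracle for the on-axis integrand: dr/ds x R
# computed numerically from the helix parameterization
cross_oracle <- function(geometry, s, z0) {
  a <- geometry$half_angle_alpha
  k <- geometry$winding_rate_k
  drds <- c(sin(a) * cos(k * s) - k * s * sin(a) * sin(k * s),
            sin(a) * sin(k * s) + k * s * sin(a) * cos(k * s),
            cos(a))
  R <- c(0, 0, z0) - unname(helix_point(geometry, s))
  c(drds[2] * R[3] - drds[3] * R[2],
    drds[3] * R[1] - drds[1] * R[3],
    drds[1] * R[2] - drds[2] * R[1])
}

# recover SAReff from one synthetic trial set the way an analyst would:
# correct, aggregate, fit the initial slope, multiply by c
recover_sar <- function(trials, heat_capacity_c, window = c(0, 1200)) {
  agg <- aggregate_trials(trials)
  sl <- initial_slope(agg$time_s, agg$mean, window = window)
  estimate_sar_eff(sl, heat_capacity_c)$sar_eff
}
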