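test_that("integrand terms match direct substitution and the cross-product oracle", {
  # s = 0 (apex): Cx = 0, Cy = -sin(a) z0, Cz = 0
  g0 <- coil_geometry(pi / 3, 0, 0.1, 5, 1)
  z0 <- 0.07
  ct <- integrand_terms(g0, 0, z0)
  expect_equal(unname(ct), c(0, -sin(pi / 3) * z0, 0), tolerance = 1e-14)

  # alpha = pi/2, k = 1, s = 2: Cz = k s^2 sin^2(a) = 4
  gz <- coil_geometry(pi / 2, 0, 2 * pi, 1, 1)
  expect_equal(unname(integrand_terms(gz, 2, 0.3)["Cz"]), 4,
               tolerance = 1e-12)

  # random points: terms equal the components of dr/ds x R
  set.seed(11)
  geo <- fix_geo()
  for (i in 1:25) {
    s <- runif(1, geo$slant_lower_s1, geo$slant_upper_s2)
    z0 <- runif(1, -0.1, 0.2)
    expect_equal(unname(integrand_terms(geo, s, z0)),
                 cross_oracle(geo, s, z0), tolerance = 1e-11)
  }
})

test_that("axial field is linear in current and zero for zero current", {
  geo0 <- fix_geo(current = 0)
  af0 <- axial_field(geo0, 0.05)
  expect_equal(c(af0$Bx, af0$By, af0$Bz), c(0, 0, 0))

  af1 <- axial_field(fix_geo(1), 0.05)
  af3 <- axial_field(fix_geo(3), 0.05)
  expect_equal(3 * c(af1$Bx, af1$By, af1$Bz), c(af3$Bx, af3$By, af3$Bz),
               tolerance = 1e-12)
})

test_that("near-circular single-turn cone reproduces the loop closed form", {
  # loop radius a, on-axis distance d: Bz = mu0 I a^2 / (2 (a^2 + d^2)^1.5)
  mu0 <- 4 * pi * 1e-7
  for (case in list(list(a = 0.05, d = 0, alpha = pi / 3),
                    list(a = 0.03, d = 0.04, alpha = pi / 4))) {
    sbar <- case$a / sin(case$alpha)
    eps <- sbar * 5e-7   # loop-width/radius < 1e-3
    g <- coil_geometry(case$alpha, sbar - eps, sbar + eps, 1, 1)
    z0 <- sbar * cos(case$alpha) + case$d
    closed <- mu0 * case$a^2 / (2 * (case$a^2 + case$d^2)^1.5)
    expect_equal(axial_field(g, z0)$Bz, closed, tolerance = 1e-4)
  }
  # a = 0.05 m, d = 0, I = 1 A: 1.2566e-5 T
  sbar <- 0.05 / sin(pi / 3)
  g <- coil_geometry(pi / 3, sbar - 2.5e-8, sbar + 2.5e-8, 1, 1)
  expect_equal(axial_field(g, sbar * cos(pi / 3))$Bz, 1.2566e-5,
               tolerance = 1e-4)
})

test_that("quadrature matches segment-summation on the axis", {
  geo <- fix_geo()
  for (z0 in c(-0.03, 0.01, 0.06, 0.13)) {
    af <- axial_field(geo, z0)
    sf <- segment_field(geo, c(0, 0, z0), segments_per_turn = 5000)
    bmag <- sqrt(sum(sf^2))
    expect_lt(max(abs(c(af$Bx, af$By, af$Bz) - sf)) / bmag, 1e-6)
  }
})

test_that("axial field errors when the observation point touches the winding", {
  g <- coil_geometry(pi / 4, 0, 0.1, 10, 1)
  expect_error(axial_field(g, 0), class = "thermosar_singular_error")
})

test_that("field grid is consistent with the axial solution and linear in current", {
  geo <- fix_geo()
  g1 <- field_grid(geo, list(x = 0, y = 0, z = 0.05),
                   guard_distance = 1e-4)
  af <- axial_field(geo, 0.05)
  expect_equal(c(g1$Bx, g1$By, g1$Bz), c(af$Bx, af$By, af$Bz),
               tolerance = 1e-4)

  spec <- list(x = seq(-0.01, 0.01, length.out = 3),
               y = seq(-0.01, 0.01, length.out = 3),
               z = seq(0.03, 0.05, length.out = 3))
  ga <- field_grid(geo, spec)
  geo2 <- fix_geo(current = 1.5)
  gb <- field_grid(geo2, spec)
  expect_equal(gb$Bx, 2 * ga$Bx, tolerance = 1e-12)
  expect_equal(gb$Bmag, 2 * ga$Bmag, tolerance = 1e-12)
})

test_that("segment refinement is converged at the default density", {
  geo <- fix_geo()
  spec <- list(x = c(-0.01, 0.01), y = 0, z = c(0.04, 0.06))
  coarse <- field_grid(geo, spec, segments_per_turn = 200,
                       guard_distance = 1e-4)
  fine <- field_grid(geo, spec, segments_per_turn = 2000,
                     guard_distance = 1e-4)
  expect_lt(max(abs(coarse$Bmag - fine$Bmag) / fine$Bmag), 1e-3)
})

test_that("nodes near the winding are masked, not filled", {
  geo <- fix_geo()
  # node right on the winding radius at mid-height
  s_mid <- 0.07
  p <- helix_point(geo, s_mid)
  g <- field_grid(geo, list(x = p["x"], y = p["y"], z = p["z"]),
                  guard_distance = 5e-3)
  expect_true(g$masked[1])
  expect_true(is.na(g$Bmag[1]))
})

test_that("nonuniformity map reproduces known gradients and a stencil oracle", {
  geo <- fix_geo()
  # uniform |B|: zero map (synthetic grid, constant field)
  spec <- list(x = seq(0, 1, length.out = 4), y = seq(0, 1, length.out = 3),
               z = seq(0, 1, length.out = 3))
  g <- field_grid(geo, spec, guard_distance = 0)
  g$Bx <- 1e-4; g$By <- 0; g$Bz <- 0; g$Bmag <- 1e-4
  nm <- nonuniformity_map(g)
  expect_true(all(abs(c(nm$gx, nm$gy, nm$gz)) < 1e-18))

  # linear ramp of |B|^2 along x: constant gradient equal to the slope
  g$Bmag <- sqrt(2 * g$x + 3)
  nm <- nonuniformity_map(g)
  expect_equal(nm$gx, rep(2, nrow(g)), tolerance = 1e-10)
  expect_equal(nm$gy, rep(0, nrow(g)), tolerance = 1e-12)

  # random grid vs brute-force stencil recomputation
  set.seed(3)
  g$Bmag <- runif(nrow(g))
  nm <- nonuniformity_map(g)
  b2 <- array(g$Bmag^2, dim = c(4, 3, 3))
  xs <- spec$x
  # brute-force central/one-sided differences along x at a few nodes
  for (j in 1:3) for (kk in 1:3) {
    expected <- c((b2[2, j, kk] - b2[1, j, kk]) / (xs[2] - xs[1]),
                  (b2[3, j, kk] - b2[1, j, kk]) / (xs[3] - xs[1]),
                  (b2[4, j, kk] - b2[2, j, kk]) / (xs[4] - xs[2]),
                  (b2[4, j, kk] - b2[3, j, kk]) / (xs[4] - xs[3]))
    got <- array(nm$gx, dim = c(4, 3, 3))[, j, kk]
    expect_equal(got, expected, tolerance = 1e-12)
  }

  # degenerate single-plane axis: zero component with a warning
  gs <- field_grid(geo, list(x = c(0, 0.01), y = 0, z = c(0.04, 0.05)),
                   guard_distance = 0)
  expect_warning(nm2 <- nonuniformity_map(gs), "single-plane")
  expect_true(all(nm2$gy == 0))
})

test_that("ROI field range handles uniform grids, single nodes and misses", {
  geo <- fix_geo()
  spec <- list(x = seq(-0.01, 0.01, length.out = 3), y = 0,
               z = seq(0.03, 0.05, length.out = 3))
  g <- field_grid(geo, spec)
  roi_all <- list(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  rr <- roi_field_range(g, roi_all)
  expect_equal(unname(rr["min"]), min(g$Bmag[!g$masked]))
  expect_equal(unname(rr["max"]), max(g$Bmag[!g$masked]))

  one <- roi_field_range(g, list(x = c(-1e-9, 1e-9), y = c(-1e-9, 1e-9),
                                 z = c(0.04 - 1e-9, 0.04 + 1e-9)))
  expect_equal(unname(one["min"]), unname(one["max"]))

  g$Bmag[] <- 1e-4  # uniform grid: min = max
  expect_equal(unname(diff(roi_field_range(g, roi_all))), 0)

  expect_error(roi_field_range(g, list(x = c(5, 6), y = c(5, 6),
                                       z = c(5, 6))),
               class = "thermosar_domain_error")
})

test_that("axial component dominates on the axis for the fixture coil", {
  geo <- fix_geo()
  for (z0 in seq(0.0, 0.12, length.out = 7)) {
    af <- axial_field(geo, z0 + 0.005)  # avoid the apex singularity at 0
    expect_lt(abs(af$Bx) / abs(af$Bz), 1)
    expect_lt(abs(af$By) / abs(af$Bz), 1)
  }
})
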