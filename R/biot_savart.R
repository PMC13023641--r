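#' Auxiliary integrand terms of the on-axis Biot--Savart integrals
#'
#' For an observation point on the symmetry axis at \code{z0}, the magnetic
#' flux density components are line integrals over the slant coordinate with
#' kernel \code{C(s) / (s^2 - 2 s z0 cos(a) + z0^2)^(3/2)}. The numerator
#' terms are the components of \code{dr/ds x R}, where \code{r(s)} is the
#' winding path and \code{R = (0, 0, z0) - r(s)}:
#' \deqn{C_x = \sin\alpha(-k s^2 \cos\alpha \cos ks + k s z_0 \cos ks +
#'   z_0 \sin ks)}
#' \deqn{C_y = \sin\alpha(-k s^2 \cos\alpha \sin ks + k s z_0 \sin ks -
#'   z_0 \cos ks)}
#' \deqn{C_z = k s^2 \sin^2\alpha}
#'
#' @param geometry a \code{\link{coil_geometry}}.
#' @param s slant coordinate(s) in m within the winding range.
#' @param z0 axial observation coordinate in m.
#' @return Matrix with columns \code{Cx, Cy, Cz} (one row per \code{s});
#'   a single \code{s} returns a named length-3 vector.
#' @export
integrand_terms <- function(geometry, s, z0) {
  stopifnot(inherits(geometry, "coil_geometry"))
  if (any(s < geometry$slant_lower_s1 - 1e-15) ||
      any(s > geometry$slant_upper_s2 + 1e-15)) {
    stop_thermosar("s outside the winding range", "thermosar_domain_error")
  }
  a <- geometry$half_angle_alpha
  k <- geometry$winding_rate_k
  sa <- sin(a); ca <- cos(a)
  cks <- cos(k * s); sks <- sin(k * s)
  out <- cbind(
    Cx = sa * (-k * s^2 * ca * cks + k * s * z0 * cks + z0 * sks),
    Cy = sa * (-k * s^2 * ca * sks + k * s * z0 * sks - z0 * cks),
    Cz = k * s^2 * sa^2
  )
  if (length(s) == 1) out[1, ] else out
}

# minimum of the kernel denominator base over the winding range;
# zero means the observation point touches the winding path extension
.min_denom <- function(geometry, z0) {
  a <- geometry$half_angle_alpha
  f <- function(s) s^2 - 2 * s * z0 * cos(a) + z0^2
  s_star <- z0 * cos(a)
  cand <- c(geometry$slant_lower_s1, geometry$slant_upper_s2)
  if (s_star >= geometry$slant_lower_s1 && s_star <= geometry$slant_upper_s2) {
    cand <- c(cand, s_star)
  }
  min(f(cand))
}

#' On-axis magnetic flux density of the conical winding
#'
#' Evaluates the Biot--Savart line integrals for an observation point on the
#' symmetry axis by adaptive quadrature. Each component equals
#' \code{mu0 I / (4 pi)} times the integral of its auxiliary term divided by
#' \code{(s^2 - 2 s z0 cos(a) + z0^2)^(3/2)} over \code{[s1, s2]}.
#'
#' @param geometry a \code{\link{coil_geometry}}; its
#'   \code{drive_current_I} sets the current.
#' @param z0 axial observation coordinate in m (scalar).
#' @param quadrature_tol relative tolerance passed to the adaptive
#'   quadrature (default \code{1e-10}).
#' @return An object of class \code{axial_field_sample}: list with
#'   \code{z0}, \code{Bx}, \code{By}, \code{Bz} in tesla.
#' @examples
#' geo <- coil_geometry(pi / 4, 0.02, 0.12, 40, 0.75)
#' axial_field(geo, z0 = 0.05)
#' @export
axial_field <- function(geometry, z0, quadrature_tol = 1e-10) {
  stopifnot(inherits(geometry, "coil_geometry"), length(z0) == 1)
  if (.min_denom(geometry, z0) <= .Machine$double.eps) {
    stop_thermosar("observation point coincides with the winding path",
                   "thermosar_singular_error")
  }
  pref <- MU0 * geometry$drive_current_I / (4 * pi)
  # integrate per quarter-turn: the integrand oscillates with the winding
  # phase, and piecewise adaptive quadrature is robust for such kernels
  n_pieces <- max(4L * geometry$n_turns_N, 4L)
  breaks <- seq(geometry$slant_lower_s1, geometry$slant_upper_s2,
                length.out = n_pieces + 1)
  comp <- function(idx) {
    f <- function(s) {
      C <- integrand_terms(geometry, s, z0)
      if (is.null(dim(C))) C <- matrix(C, nrow = 1)
      a <- geometry$half_angle_alpha
      den <- (s^2 - 2 * s * z0 * cos(a) + z0^2)^1.5
      C[, idx] / den
    }
    total <- 0
    for (i in seq_len(n_pieces)) {
      lo <- breaks[i]
      hi <- breaks[i + 1]
      scale <- max(abs(f(seq(lo, hi, length.out = 7)))) * (hi - lo)
      total <- total + stats::integrate(
        f, lo, hi, rel.tol = quadrature_tol,
        abs.tol = max(scale, 1e-300) * quadrature_tol,
        subdivisions = 200L, stop.on.error = TRUE)$value
    }
    total
  }
  structure(
    list(z0 = z0,
         Bx = pref * comp(1), By = pref * comp(2), Bz = pref * comp(3)),
    class = "axial_field_sample"
  )
}

#' Discretize the winding into straight segments
#'
#' Helper for the segment-summation Biot--Savart evaluation: returns segment
#' midpoints and vector lengths \code{dl} of the helix split into
#' \code{n_segments} equal slant steps.
#'
#' @param geometry a \code{\link{coil_geometry}}.
#' @param n_segments total number of straight segments.
#' @return List with matrices \code{mid} (n x 3, m) and \code{dl} (n x 3, m).
#' @export
helix_segments <- function(geometry, n_segments) {
  s <- seq(geometry$slant_lower_s1, geometry$slant_upper_s2,
           length.out = n_segments + 1)
  pts <- helix_point(geometry, s)
  list(mid = (pts[-1, , drop = FALSE] + pts[-(n_segments + 1), , drop = FALSE]) / 2,
       dl = pts[-1, , drop = FALSE] - pts[-(n_segments + 1), , drop = FALSE])
}

# B at a single point r0 (length-3) by straight-segment summation,
# given precomputed segments; returns c(Bx, By, Bz) in T
.segment_field_point <- function(seg, r0, current) {
  Rx <- r0[1] - seg$mid[, 1]
  Ry <- r0[2] - seg$mid[, 2]
  Rz <- r0[3] - seg$mid[, 3]
  rr <- (Rx^2 + Ry^2 + Rz^2)^1.5
  cx <- seg$dl[, 2] * Rz - seg$dl[, 3] * Ry
  cy <- seg$dl[, 3] * Rx - seg$dl[, 1] * Rz
  cz <- seg$dl[, 1] * Ry - seg$dl[, 2] * Rx
  MU0 * current / (4 * pi) * c(sum(cx / rr), sum(cy / rr), sum(cz / rr))
}

#' Magnetic field on a point set by segment summation
#'
#' Evaluates the Biot--Savart field of the discretized winding at arbitrary
#' points (the numerical extension used off the symmetry axis, where the
#' on-axis integrals do not apply).
#'
#' @param geometry a \code{\link{coil_geometry}}.
#' @param points n x 3 matrix of observation points (m).
#' @param segments_per_turn straight segments per winding turn (default 200).
#' @return n x 3 matrix with columns \code{Bx, By, Bz} (T).
#' @export
segment_field <- function(geometry, points, segments_per_turn = 200) {
  points <- rbind(points)
  seg <- helix_segments(geometry,
                        n_segments = segments_per_turn * geometry$n_turns_N)
  out <- t(apply(points, 1, .segment_field_point, seg = seg,
                 current = geometry$drive_current_I))
  colnames(out) <- c("Bx", "By", "Bz")
  out
}

#' Magnetic field on a regular 3-D grid
#'
#' Computes \code{B} at every node of an axis-aligned lattice by
#' straight-segment Biot--Savart summation. Nodes closer to the winding path
#' than a guard distance (default twice the largest grid spacing) are masked
#' (set to \code{NA}) and flagged rather than filled with near-singular
#' values.
#'
#' @param geometry a \code{\link{coil_geometry}}.
#' @param grid_spec list with numeric vectors \code{x}, \code{y}, \code{z}
#'   giving the lattice coordinates per axis (m).
#' @param segments_per_turn straight segments per winding turn (default 200).
#' @param guard_distance guard radius around the winding in m; default
#'   2 x the largest spacing among the lattice axes.
#' @return An object of class \code{field_grid}: data frame with columns
#'   \code{x, y, z, Bx, By, Bz, Bmag, masked}, plus attributes
#'   \code{axes} (the lattice coordinate vectors) and \code{provenance}.
#' @export
field_grid <- function(geometry, grid_spec, segments_per_turn = 200,
                       guard_distance = NULL) {
  stopifnot(is.list(grid_spec), all(c("x", "y", "z") %in% names(grid_spec)))
  ax <- lapply(grid_spec[c("x", "y", "z")], as.numeric)
  spacing <- vapply(ax, function(v) if (length(v) > 1) min(diff(v)) else 0,
                    numeric(1))
  if (any(spacing < 0)) {
    stop_thermosar("grid axes must be increasing", "thermosar_validation_error")
  }
  if (is.null(guard_distance)) {
    guard_distance <- 2 * max(spacing, 0)
  }
  nodes <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z,
                                 KEEP.OUT.ATTRS = FALSE))
  seg <- helix_segments(geometry,
                        n_segments = segments_per_turn * geometry$n_turns_N)
  n <- nrow(nodes)
  B <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("Bx", "By", "Bz")))
  masked <- logical(n)
  for (i in seq_len(n)) {
    d2 <- (nodes[i, 1] - seg$mid[, 1])^2 + (nodes[i, 2] - seg$mid[, 2])^2 +
      (nodes[i, 3] - seg$mid[, 3])^2
    if (min(d2) < guard_distance^2) {
      masked[i] <- TRUE
    } else {
      B[i, ] <- .segment_field_point(seg, nodes[i, ], geometry$drive_current_I)
    }
  }
  out <- data.frame(nodes, B,
                    Bmag = sqrt(rowSums(B^2)), masked = masked)
  structure(out,
            class = c("field_grid", "data.frame"),
            axes = ax,
            provenance = list(geometry = geometry,
                              segments_per_turn = segments_per_turn,
                              guard_distance = guard_distance))
}

#' Spatial gradient of the squared field magnitude
#'
#' Dielectrophoretic forces on polarizable constituents scale with the
#' gradient of the squared field magnitude; this computes the geometric
#' non-uniformity surrogate \code{grad |B|^2} on the grid by central
#' differences (one-sided at the lattice boundaries). An axis with a single
#' plane contributes a zero component, with a warning.
#'
#' @param grid a \code{\link{field_grid}}.
#' @return Data frame with columns \code{x, y, z, gx, gy, gz} (T^2/m), same
#'   node order as \code{grid}.
#' @export
nonuniformity_map <- function(grid) {
  stopifnot(inherits(grid, "field_grid"))
  ax <- attr(grid, "axes")
  dims <- vapply(ax, length, integer(1))
  if (all(dims < 2)) {
    stop_thermosar("grid needs >= 2 nodes along at least one axis",
                   "thermosar_validation_error")
  }
  b2 <- array(grid$Bmag^2, dim = dims)
  grad_axis <- function(arr, axis, coords) {
    n <- dim(arr)[axis]
    if (n < 2) {
      warning("single-plane axis '", c("x", "y", "z")[axis],
              "': gradient component reported as zero")
      return(array(0, dim = dim(arr)))
    }
    idx <- function(i) {
      sel <- rep(list(quote(expr = )), 3)
      sel[[axis]] <- i
      do.call(`[`, c(list(arr), sel, list(drop = FALSE)))
    }
    g <- array(NA_real_, dim = dim(arr))
    assign_slice <- function(g, i, val) {
      sel <- rep(list(quote(expr = )), 3)
      sel[[axis]] <- i
      do.call(`[<-`, c(list(g), sel, list(val)))
    }
    # interior: central differences
    if (n > 2) {
      for (i in 2:(n - 1)) {
        g <- assign_slice(g, i, (idx(i + 1) - idx(i - 1)) /
                            (coords[i + 1] - coords[i - 1]))
      }
    }
    g <- assign_slice(g, 1, (idx(2) - idx(1)) / (coords[2] - coords[1]))
    g <- assign_slice(g, n, (idx(n) - idx(n - 1)) / (coords[n] - coords[n - 1]))
    g
  }
  data.frame(x = grid$x, y = grid$y, z = grid$z,
             gx = as.vector(grad_axis(b2, 1, ax$x)),
             gy = as.vector(grad_axis(b2, 2, ax$y)),
             gz = as.vector(grad_axis(b2, 3, ax$z)))
}

#' Field-magnitude range over a region of interest
#'
#' @param grid a \code{\link{field_grid}}.
#' @param roi list with length-2 numeric vectors \code{x}, \code{y},
#'   \code{z}: the axis-aligned bounds of the box (m).
#' @return Named numeric vector \code{c(min = , max = )} of \code{|B|} in T
#'   over the unmasked nodes inside the ROI.
#' @export
roi_field_range <- function(grid, roi) {
  stopifnot(inherits(grid, "field_grid"))
  sel <- grid$x >= roi$x[1] & grid$x <= roi$x[2] &
    grid$y >= roi$y[1] & grid$y <= roi$y[2] &
    grid$z >= roi$z[1] & grid$z <= roi$z[2] & !grid$masked
  if (!any(sel)) {
    stop_thermosar("ROI contains no unmasked grid nodes",
                   "thermosar_domain_error")
  }
  c(min = min(grid$Bmag[sel]), max = max(grid$Bmag[sel]))
}

#' Write a field grid to CSV with a JSON metadata sidecar
#'
#' @param grid a \code{\link{field_grid}}.
#' @param path output CSV path; the sidecar is written next to it with
#'   extension \code{.json}.
#' @return Invisibly, the CSV path.
#' @export
write_field_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  prov <- attr(grid, "provenance")
  meta <- list(
    geometry = unclass(prov$geometry),
    segments_per_turn = prov$segments_per_turn,
    guard_distance = prov$guard_distance,
    n_nodes = nrow(grid),
    n_masked = sum(grid$masked)
  )
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
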