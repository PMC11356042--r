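# Magnetostatics of planar spiral microcoils.
#
# Every material present (copper, PDMS, sweat, dilute MNP suspension) has
# relative permeability ~1, so the source field decouples from the particles
# and the vector-potential problem reduces to Biot-Savart superposition of
# circular current filaments, for which the exact solution in complete
# elliptic integrals is used.  B = mu0 * H everywhere outside the wires.

# field of a circular filament of radius a at height z_loop carrying unit
# current, evaluated at cylindrical (rho, z); returns cbind(Brho, Bz) per amp.
# Vectorized over points; 'a' may be scalar or same length as rho.
.loop_Brz_unit <- function(a, rho, z) {
  denom <- (a + rho)^2 + z^2
  m <- 4 * a * rho / denom
  # clamp roundoff at the m -> 1 end (point close to the filament ring)
  m <- pmin(pmax(m, 0), 1 - 1e-14)
  ke <- pracma::ellipke(m)
  K <- ke$k; E <- ke$e
  pref <- .mu0 / (2 * pi * sqrt(denom))
  d2 <- (a - rho)^2 + z^2
  Bz <- pref * (K + (a^2 - rho^2 - z^2) / d2 * E)
  Brho <- ifelse(rho < 1e-12, 0,
                 pref * z / pmax(rho, 1e-12) *
                   (-K + (a^2 + rho^2 + z^2) / d2 * E))
  cbind(Brho, Bz)
}

.check_filament_distance <- function(a, z_loop, points) {
  rho <- sqrt(points[, 1]^2 + points[, 2]^2)
  d <- sqrt((rho - a)^2 + (points[, 3] - z_loop)^2)
  if (any(d < 1e-9))
    stop("field point lies on (or within 1 nm of) a current filament",
         call. = FALSE)
}

#' Magnetic field of a single circular current loop
#'
#' Exact field of a circular filament (axis along `z`, centered on the
#' origin) from the standard complete-elliptic-integral solution.
#'
#' @param radius Loop radius (m).
#' @param current Loop current (A).
#' @param points Point `c(x, y, z)` or an n x 3 matrix (m).
#' @param loop_z Axial position of the loop plane (m).
#' @return A `field_sample` data frame with columns `x, y, z, Bx, By, Bz`
#'   (tesla) and `Hx, Hy, Hz` (A/m); `B = mu0 * H`.
#' @export
#' @examples
#' loop_field(100e-6, 0.4, c(0, 0, 0))$Bz  # mu0*I/(2a) = 2.513 mT
loop_field <- function(radius, current, points, loop_z = 0) {
  .check_positive(radius, "radius")
  points <- .as_points(points)
  .check_filament_distance(radius, loop_z, points)
  rho <- sqrt(points[, 1]^2 + points[, 2]^2)
  f <- .loop_Brz_unit(radius, rho, points[, 3] - loop_z) * current
  ux <- ifelse(rho > 0, points[, 1] / rho, 0)
  uy <- ifelse(rho > 0, points[, 2] / rho, 0)
  B <- cbind(f[, 1] * ux, f[, 1] * uy, f[, 2])
  structure(data.frame(x = points[, 1], y = points[, 2], z = points[, 3],
                       Bx = B[, 1], By = B[, 2], Bz = B[, 3],
                       Hx = B[, 1] / .mu0, Hy = B[, 2] / .mu0,
                       Hz = B[, 3] / .mu0),
            class = c("field_sample", "data.frame"))
}

# filament table of a coil: one centerline filament per turn, or an
# n_sub x n_sub sub-filament grid across each 10 x 10 um wire cross-section
# (midpoint rule), each carrying current / n_sub^2.  Needed to resolve the
# near-field ripple at the wire pitch.
.filament_table <- function(coil, quadrature = FALSE, n_sub = 3L) {
  loops <- derive_loop_set(coil)
  if (!quadrature)
    return(data.frame(radius = loops$radius, z = loops$z,
                      current = rep(coil$current, nrow(loops))))
  off <- ((seq_len(n_sub) - 0.5) / n_sub - 0.5)
  dr <- off * coil$wire_width
  dz <- off * coil$wire_height
  grid <- expand.grid(dr = dr, dz = dz)
  data.frame(
    radius = rep(loops$radius, each = nrow(grid)) + grid$dr,
    z = rep(loops$z, each = nrow(grid)) + grid$dz,
    current = coil$current / n_sub^2)
}

# raw field of a coil as an n x 3 matrix of B (tesla); internal workhorse
.coil_B <- function(coil, points, quadrature = FALSE, n_sub = 3L,
                    current = NULL) {
  fil <- .filament_table(coil, quadrature, n_sub)
  if (!is.null(current)) fil$current <- fil$current * 0 + current *
      (if (quadrature) 1 / n_sub^2 else 1)
  rho <- sqrt(points[, 1]^2 + points[, 2]^2)
  z <- points[, 3]
  if (quadrature) {
    # reject points inside any wire volume
    loops <- derive_loop_set(coil)
    for (i in seq_len(nrow(loops))) {
      inside <- abs(rho - loops$radius[i]) < coil$wire_width / 2 &
        abs(z - loops$z[i]) < coil$wire_height / 2
      if (any(inside))
        stop("field point lies inside a wire volume", call. = FALSE)
    }
  }
  Brho <- numeric(nrow(points)); Bz <- numeric(nrow(points))
  for (i in seq_len(nrow(fil))) {
    .check_filament_distance(fil$radius[i], fil$z[i], points)
    f <- .loop_Brz_unit(fil$radius[i], rho, z - fil$z[i]) * fil$current[i]
    Brho <- Brho + f[, 1]
    Bz <- Bz + f[, 2]
  }
  ux <- ifelse(rho > 0, points[, 1] / rho, 0)
  uy <- ifelse(rho > 0, points[, 2] / rho, 0)
  cbind(Brho * ux, Brho * uy, Bz)
}

#' Magnetic field of a spiral coil on a set of points
#'
#' Linear superposition of the elliptic-integral filament fields of all
#' turns.  With `quadrature = TRUE` each wire's rectangular cross-section is
#' represented by an `n_sub` x `n_sub` sub-filament grid carrying
#' `current / n_sub^2` each, which is required to resolve the near-field
#' ripple at the wire pitch; a single centerline filament per turn (the
#' default) is accurate in the far field and much faster.
#'
#' @param coil A [coil_spec()].
#' @param points Point `c(x, y, z)` or an n x 3 matrix (m).
#' @param quadrature Logical; use wire cross-section sub-filaments.
#' @param n_sub Sub-filament grid order per wire.
#' @param gradient Logical; also return the Cartesian gradient of `|H|^2`
#'   (columns `gHx, gHy, gHz`, A^2/m^3), computed by central differences with
#'   step `grad_step`.
#' @param grad_step Central-difference step for the gradient (m).
#' @return A `field_map` data frame with columns `x, y, z, Bx, By, Bz, Hx,
#'   Hy, Hz` (and the gradient columns when requested); the quadrature flag
#'   is recorded in `attr(, "quadrature")`.
#' @export
coil_field <- function(coil, points, quadrature = FALSE, n_sub = 3L,
                       gradient = FALSE, grad_step = 1e-6) {
  stopifnot(inherits(coil, "coil_spec"))
  points <- .as_points(points)
  B <- .coil_B(coil, points, quadrature, n_sub)
  out <- data.frame(x = points[, 1], y = points[, 2], z = points[, 3],
                    Bx = B[, 1], By = B[, 2], Bz = B[, 3],
                    Hx = B[, 1] / .mu0, Hy = B[, 2] / .mu0,
                    Hz = B[, 3] / .mu0)
  if (gradient) {
    g <- grad_H2(coil, points, step = grad_step, quadrature = quadrature,
                 n_sub = n_sub)
    out$gHx <- g[, 1]; out$gHy <- g[, 2]; out$gHz <- g[, 3]
  }
  structure(out, quadrature = quadrature,
            class = c("field_map", "data.frame"))
}

#' Gradient of the squared magnetic field strength
#'
#' Central-difference gradient of `|H|^2` of a spiral coil, the field
#' quantity that drives the magnetophoretic force.
#'
#' @inheritParams coil_field
#' @param step Central-difference step (m); 1 um by default.
#' @return An n x 3 matrix (A^2/m^3).
#' @export
grad_H2 <- function(coil, points, step = 1e-6, quadrature = FALSE,
                    n_sub = 3L) {
  points <- .as_points(points)
  h2 <- function(p) {
    B <- .coil_B(coil, p, quadrature, n_sub)
    (B[, 1]^2 + B[, 2]^2 + B[, 3]^2) / .mu0^2
  }
  g <- matrix(0, nrow(points), 3L)
  for (k in 1:3) {
    dp <- matrix(0, nrow(points), 3L); dp[, k] <- step
    g[, k] <- (h2(points + dp) - h2(points - dp)) / (2 * step)
  }
  g
}

#' Magnetic field of a straight current segment
#'
#' Exact Biot-Savart field of a finite straight filament, used to add the
#' coil feed lines: two feed segments break the axisymmetry of the spiral
#' field and reproduce the field asymmetry seen across a channel aligned
#' parallel to the vias.
#'
#' @param start,end Segment end points `c(x, y, z)` (m).
#' @param current Current flowing from `start` to `end` (A).
#' @param points Point `c(x, y, z)` or an n x 3 matrix (m).
#' @return An n x 3 matrix of B (tesla).
#' @export
segment_field <- function(start, end, current, points) {
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(length(start) == 3L, length(end) == 3L)
  points <- .as_points(points)
  ab <- end - start
  L <- sqrt(sum(ab^2))
  if (L <= 0) stop("segment has zero length", call. = FALSE)
  u <- ab / L
  ap <- sweep(points, 2L, start)                  # start -> point
  s <- drop(ap %*% u)                             # axial coordinate
  perp <- ap - outer(s, u)                        # perpendicular offset
  rho <- sqrt(rowSums(perp^2))
  on_axis <- rho < 1e-12
  if (any(rho < 1e-9 & s >= -1e-9 & s <= L + 1e-9))
    stop("field point lies on (or within 1 nm of) the segment", call. = FALSE)
  sin1 <- -s / sqrt(s^2 + rho^2)
  sin2 <- (L - s) / sqrt((L - s)^2 + rho^2)
  mag <- .mu0 * current / (4 * pi * pmax(rho, 1e-12)) * (sin2 - sin1)
  # azimuthal direction u x rho_hat
  rh <- perp / pmax(rho, 1e-12)
  phi <- cbind(u[2] * rh[, 3] - u[3] * rh[, 2],
               u[3] * rh[, 1] - u[1] * rh[, 3],
               u[1] * rh[, 2] - u[2] * rh[, 1])
  B <- phi * mag
  B[on_axis, ] <- 0
  B
}

#' Flux-density profile along a coordinate axis
#'
#' Samples `Bz` and `Bx` along a line parallel to the `x` axis (at fixed
#' `y, z`) or the `z` axis (at fixed `x, y`), the raw material for the field
#' uniformity and ripple analyses.
#'
#' @param coil A [coil_spec()].
#' @param axis `"x"` (radial path at fixed height) or `"z"` (vertical decay
#'   path).
#' @param range Numeric length-2 sampling interval along `axis` (m).
#' @param fixed Named numeric vector fixing the other coordinates, e.g.
#'   `c(y = 0, z = 30e-6)` for an `x` profile.
#' @param n Number of equally spaced samples.
#' @param quadrature,n_sub Wire cross-section quadrature (see [coil_field()]).
#' @param feeds Optional list of feed-line segments, each a
#'   `list(start =, end =)` pair in metres, added via [segment_field()].
#' @return A data frame with columns `coord` (m), `Bz`, `Bx` (tesla), with the
#'   sample spacing in `attr(, "spacing")`.
#' @export
bz_profile <- function(coil, axis = c("x", "z"), range, fixed = c(y = 0),
                       n = 201L, quadrature = FALSE, n_sub = 3L,
                       feeds = NULL) {
  axis <- match.arg(axis)
  stopifnot(length(range) == 2L, is.numeric(range))
  coord <- seq(range[1], range[2], length.out = n)
  fx <- function(name, default = 0)
    if (name %in% names(fixed)) unname(fixed[[name]]) else default
  points <- switch(axis,
    x = cbind(coord, fx("y"), fx("z", 30e-6)),
    z = cbind(fx("x"), fx("y"), coord))
  B <- .coil_B(coil, points, quadrature, n_sub)
  if (!is.null(feeds))
    for (f in feeds)
      B <- B + segment_field(f$start, f$end, coil$current, points)
  structure(data.frame(coord = coord, Bz = B[, 3], Bx = B[, 1]),
            spacing = coord[2] - coord[1], axis = axis,
            class = c("bz_profile", "data.frame"))
}

#' Near-field ripple metric of a flux-density profile
#'
#' The close spacing of the coil turns imprints a spatial oscillation
#' ("ripple") on the flux density at the wire pitch that decays with height.
#' The metric is the peak-to-peak amplitude of the oscillatory component --
#' the profile minus a moving-average baseline whose window is one wire
#' pitch -- divided by the mean flux density over the span.
#'
#' @param profile A [bz_profile()] over the turns' radial span, sampled with
#'   cross-section quadrature enabled.
#' @param pitch Wire pitch (m), `wire_width + spacing`.
#' @return Dimensionless relative peak-to-peak ripple.
#' @export
ripple_metric <- function(profile, pitch) {
  stopifnot(is.data.frame(profile), all(c("coord", "Bz") %in% names(profile)))
  .check_positive(pitch, "pitch")
  spacing <- attr(profile, "spacing")
  if (is.null(spacing)) spacing <- diff(profile$coord[1:2])
  span <- diff(range(profile$coord))
  if (span < 5 * pitch)
    stop(sprintf("profile span (%.3g m) must cover at least 5 wire pitches (%.3g m)",
                 span, 5 * pitch), call. = FALSE)
  w <- max(3L, round(pitch / spacing))
  if (w %% 2L == 0L) w <- w + 1L
  kern <- rep(1 / w, w)
  baseline <- stats::filter(profile$Bz, kern, sides = 2L)
  keep <- !is.na(baseline)
  resid <- profile$Bz[keep] - baseline[keep]
  if (!length(resid)) stop("profile too short for the baseline window",
                           call. = FALSE)
  (max(resid) - min(resid)) / abs(mean(profile$Bz[keep]))
}

#' DC resistance of a spiral coil
#'
#' Sum of the filament centerline lengths over the conductor cross-section:
#' `R = sum(2 pi r_k) / (sigma w h)`.
#'
#' @param coil A [coil_spec()].
#' @return Resistance (ohm).
#' @export
coil_resistance <- function(coil) {
  stopifnot(inherits(coil, "coil_spec"))
  area <- coil$wire_width * coil$wire_height
  if (area <= 0) stop("wire cross-section must be positive", call. = FALSE)
  sum(2 * pi * derive_loop_set(coil)$radius) / (coil$conductivity * area)
}

#' Power merit factor of a coil
#'
#' `Mp = Bmax / P` with `P = U * I = I^2 * R`: the maximum flux density the
#' coil delivers to the fluidic domain per watt dissipated.  `Bmax` is the
#' maximum of `|B|` over the channel-floor plane `z = z_plane`, located by a
#' radial grid search (the field is axisymmetric without feed lines).
#'
#' @param coil A [coil_spec()].
#' @param current Drive current (A); defaults to the coil's.
#' @param z_plane Evaluation plane height above the wire top surface (m);
#'   defaults to the 30 um reference separation.
#' @param grid_step Radial search step (m).
#' @return A `merit_result` list with `Bmax` (T), `Bmax_rho` (m),
#'   `resistance` (ohm), `voltage` (V), `power` (W), `Mp` (T/W).
#' @export
power_merit <- function(coil, current = coil$current, z_plane = 30e-6,
                        grid_step = 1e-6) {
  stopifnot(inherits(coil, "coil_spec"))
  .check_positive(current, "current")
  .check_positive(z_plane, "z_plane")
  rho <- seq(0, coil$outer_radius + 50e-6, by = grid_step)
  points <- cbind(rho, 0, z_plane)
  B <- .coil_B(coil, points, quadrature = FALSE, current = current)
  Bmag <- sqrt(rowSums(B^2))
  i <- which.max(Bmag)
  R <- coil_resistance(coil)
  U <- current * R
  P <- U * current
  structure(list(Bmax = Bmag[i], Bmax_rho = rho[i], resistance = R,
                 voltage = U, power = P, Mp = Bmag[i] / P),
            class = "merit_result")
}

#' @export
print.merit_result <- function(x, ...) {
  cat(sprintf("<merit_result> Bmax = %.3g mT at rho = %.0f um; R = %.1f ohm, P = %.3g W, Mp = %.3g T/W\n",
              x$Bmax * 1e3, x$Bmax_rho * 1e6, x$resistance, x$power, x$Mp))
  invisible(x)
}
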