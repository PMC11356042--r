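# Steady laminar flow of sweat in the rectangular microchannel.
#
# At the device's Reynolds number (~0.3) the Navier-Stokes momentum balance
# reduces to steady, fully developed, unidirectional Poiseuille flow, whose
# exact solution in a rectangular duct is the classical Fourier series for
# the Poisson problem  laplacian(s) = -1  with no-slip walls:
#
#   s(y, z) = sum_{n odd} (4 H^2 / (n pi)^3)
#             [1 - cosh(n pi y / H) / cosh(n pi b / H)] sin(n pi z / H)
#
# with b = W/2 the half-width.  The physical velocity is u = (G/eta) s with
# G = -dp/dx chosen so that the integrated flux equals the prescribed Q;
# flux conservation is therefore exact by construction up to series
# truncation.

# cosh(x)/cosh(X) without overflow for large arguments
.cosh_ratio <- function(x, X) {
  x <- pmin(abs(x), X)
  if (X > 30) exp(x - X) * (1 + exp(-2 * x)) / (1 + exp(-2 * X))
  else cosh(x) / cosh(X)
}

# shape function s(y, z) (m^2); y in [-W/2, W/2], zloc in [0, H]
.duct_shape <- function(y, zloc, W, H, terms) {
  n <- seq(1L, terms, by = 2L)
  s <- 0
  for (k in n) {
    a <- k * pi / H
    s <- s + (4 * H^2 / (k * pi)^3) *
      (1 - .cosh_ratio(a * y, a * W / 2)) * sin(a * zloc)
  }
  s
}

# analytic flux of the shape function (m^4)
.duct_shape_flux <- function(W, H, terms) {
  n <- seq(1L, terms, by = 2L)
  sum((4 * H^2 / (n * pi)^3) * (2 * H / (n * pi)) *
        (W - (2 * H / (n * pi)) * tanh(n * pi * W / (2 * H))))
}

#' Solve the laminar duct flow of the microchannel
#'
#' Returns the steady fully developed axial velocity field `u(y, z)` scaled
#' so that the integrated flux equals the prescribed flow rate.
#'
#' @param channel A [channel_spec()].
#' @param fluid A [fluid_spec()].
#' @param series_terms Highest Fourier term (odd, >= 11); truncation error
#'   decays like `1/n^3`.
#' @return A `flow_field` object with elements `channel`, `fluid`,
#'   `mean_velocity` (m/s), `max_velocity` (m/s), `pressure_gradient`
#'   (Pa/m, the magnitude of dp/dx), `reynolds` (on the hydraulic diameter)
#'   and the series parameters.
#' @export
#' @examples
#' fl <- solve_flow(channel_spec(50e-6, 50e-6, 1e-3, 30e-6), fluid_spec())
#' fl$mean_velocity  # Q / (W * H) = 6.67 mm/s
solve_flow <- function(channel, fluid, series_terms = 51L) {
  stopifnot(inherits(channel, "channel_spec"), inherits(fluid, "fluid_spec"))
  series_terms <- .check_count(series_terms, "series_terms")
  if (series_terms < 11L || series_terms %% 2L == 0L)
    stop("'series_terms' must be an odd integer >= 11", call. = FALSE)
  W <- channel$width; H <- channel$height; Q <- fluid$flow_rate
  flux_shape <- .duct_shape_flux(W, H, series_terms)
  G <- fluid$viscosity * Q / flux_shape   # -dp/dx
  scale <- G / fluid$viscosity            # u = scale * shape
  umean <- Q / (W * H)
  umax <- scale * .duct_shape(0, H / 2, W, H, series_terms)
  Dh <- 2 * W * H / (W + H)
  Re <- fluid$density * umean * Dh / fluid$viscosity
  structure(list(channel = channel, fluid = fluid,
                 series_terms = series_terms, scale = scale,
                 mean_velocity = umean, max_velocity = umax,
                 pressure_gradient = G, reynolds = Re),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %.0f x %.0f um duct, Q = %.3g uL/min: u_mean = %.3g mm/s, u_max = %.3g mm/s, Re = %.3g\n",
              x$channel$width * 1e6, x$channel$height * 1e6,
              x$fluid$flow_rate * 6e10, x$mean_velocity * 1e3,
              x$max_velocity * 1e3, x$reynolds))
  invisible(x)
}

#' Fluid velocity at points inside the channel
#'
#' Evaluates the series solution at device coordinates: `y` lateral about the
#' channel axis, `z` vertical with the channel floor at
#' `z = coil_separation`.  The velocity is axial, `(u, 0, 0)`.
#'
#' @param flow A [solve_flow()] result.
#' @param points Point `c(x, y, z)` or an n x 3 matrix (m).
#' @return An n x 3 matrix of velocity (m/s).
#' @export
velocity_at <- function(flow, points) {
  stopifnot(inherits(flow, "flow_field"))
  points <- .as_points(points)
  ch <- flow$channel
  yloc <- points[, 2] - ch$lateral_offset
  zloc <- points[, 3] - ch$coil_separation
  b <- ch$width / 2
  tol <- 1e-12
  if (any(yloc < -b - tol | yloc > b + tol))
    stop(sprintf("point outside channel: |y - lateral_offset| must be <= width/2 = %.3g m",
                 b), call. = FALSE)
  if (any(zloc < -tol | zloc > ch$height + tol))
    stop(sprintf("point outside channel: z must lie in [coil_separation, coil_separation + height] = [%.3g, %.3g] m",
                 ch$coil_separation, ch$coil_separation + ch$height),
         call. = FALSE)
  yloc <- pmin(pmax(yloc, -b), b)
  zloc <- pmin(pmax(zloc, 0), ch$height)
  u <- flow$scale * .duct_shape(yloc, zloc, ch$width, ch$height,
                                flow$series_terms)
  unname(cbind(u, 0, 0))
}
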