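# Independent numerical oracles used by the property tests.

# Biot-Savart line integral of a circular loop (midpoint rule with exact
# tangents, n nodes) -- independent of the elliptic-integral solution.
oracle_loop_field <- function(radius, current, point, n = 720L) {
  mu0 <- 4e-7 * pi
  th <- (seq_len(n) - 0.5) / n * 2 * pi
  src <- cbind(radius * cos(th), radius * sin(th), 0)
  tangent <- cbind(-sin(th), cos(th), 0) * (2 * pi * radius / n)
  rvec <- sweep(-src, 2L, point, `+`)      # point - src
  rn <- sqrt(rowSums(rvec^2))
  crossp <- cbind(tangent[, 2] * rvec[, 3] - tangent[, 3] * rvec[, 2],
                  tangent[, 3] * rvec[, 1] - tangent[, 1] * rvec[, 3],
                  tangent[, 1] * rvec[, 2] - tangent[, 2] * rvec[, 1])
  mu0 * current / (4 * pi) * colSums(crossp / rn^3)
}

# Finite-difference Poisson solve of the duct-flow shape problem
# (laplacian s = -1, no-slip walls) on an n x n grid, scaled to flow rate Q.
oracle_duct_velocity <- function(W, H, Q, n = 201L) {
  y <- seq(-W / 2, W / 2, length.out = n)
  z <- seq(0, H, length.out = n)
  hy <- y[2] - y[1]; hz <- z[2] - z[1]
  ni <- n - 2L
  NN <- ni * ni
  I <- rep(seq_len(ni), times = ni)
  J <- rep(seq_len(ni), each = ni)
  k <- (J - 1L) * ni + I
  A <- Matrix::sparseMatrix(i = k, j = k, x = rep(-2 / hy^2 - 2 / hz^2, NN),
                            dims = c(NN, NN))
  for (shift in list(c(-1L, 0L, 1 / hy^2), c(1L, 0L, 1 / hy^2),
                     c(0L, -1L, 1 / hz^2), c(0L, 1L, 1 / hz^2))) {
    keep <- I + shift[1] >= 1 & I + shift[1] <= ni &
      J + shift[2] >= 1 & J + shift[2] <= ni
    A <- A + Matrix::sparseMatrix(
      i = k[keep], j = (J[keep] + shift[2] - 1L) * ni + I[keep] + shift[1],
      x = rep(shift[3], sum(keep)), dims = c(NN, NN))
  }
  s <- matrix(0, n, n)
  s[2:(n - 1), 2:(n - 1)] <- matrix(as.numeric(Matrix::solve(A, rep(-1, NN))),
                                    ni, ni)
  flux <- sum(s) * hy * hz
  list(y = y, z = z, u = Q / flux * s)
}

# a low-flow operating point where magnetophoresis competes with advection;
# used to exercise the trapping, release and readout code paths
lowflow_config <- function(coil_name = "R500", flow_uL_min = 0.02,
                           coil_separation = 30e-6, diameter = 50e-9,
                           horizon = 40, ...) {
  base <- default_device_config(coil_name)
  device_config(
    base$coil,
    channel_spec(50e-6, 50e-6, base$channel$length, coil_separation),
    fluid_spec(flow_rate = flow_uL_min * 1e-9 / 60),
    particle_spec(diameter = diameter),
    sim = sim_control(horizon = horizon, ...))
}
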