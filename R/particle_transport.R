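# Lagrangian transport of magnetic nanoparticles.
#
# An MNP in the channel feels the magnetophoretic force
#
#   Fmap = 1/4 pi mu_r mu0 D^3 (mu_rp - mu_r)/(mu_rp + 2 mu_r) grad(|H|^2)
#
# and Stokes drag FD = 6 pi eta r (u - vp).  The momentum relaxation time
# m/(6 pi eta r) ~ 7e-10 s is vastly shorter than any flow timescale
# (Stokes number << 1), so the inertial equation is reduced to its
# overdamped limit  vp = u + Fmap/(6 pi eta r)  and integrated with an
# adaptive Cash-Karp Runge-Kutta scheme; the full inertial system is kept
# (via deSolve) solely as a cross-check oracle.

#' Magnetophoretic force on a particle
#'
#' Dipole force on a magnetizable sphere in a field gradient, with the
#' Clausius-Mossotti contrast factor
#' `(mu_rp - mu_r) / (mu_rp + 2 mu_r)` setting sign and magnitude.
#'
#' @param particle A [particle_spec()].
#' @param fluid A [fluid_spec()].
#' @param gradH2 Gradient of `|H|^2`, a length-3 vector or n x 3 matrix
#'   (A^2/m^3).
#' @return Force in newtons, same shape as `gradH2`.
#' @export
#' @examples
#' p <- particle_spec(50e-9)
#' magnetophoretic_force(p, fluid_spec(), c(0, 0, 1e16))  # ~1.233e-12 N along z
magnetophoretic_force <- function(particle, fluid, gradH2) {
  stopifnot(inherits(particle, "particle_spec"), inherits(fluid, "fluid_spec"))
  mur <- fluid$rel_permeability
  murp <- particle$rel_permeability
  if (abs(murp + 2 * mur) < .Machine$double.eps)
    stop("degenerate contrast: mu_rp + 2 mu_r must be nonzero", call. = FALSE)
  cm <- (murp - mur) / (murp + 2 * mur)
  pref <- 0.25 * pi * mur * .mu0 * particle$diameter^3 * cm
  if (is.null(dim(gradH2))) pref * as.numeric(gradH2) else pref * gradH2
}

#' Stokes drag force on a particle
#'
#' `FD = 6 pi eta r (u - vp)` with `r = diameter / 2`.
#'
#' @param particle A [particle_spec()].
#' @param fluid A [fluid_spec()].
#' @param u_fluid Fluid velocity, length-3 vector or n x 3 matrix (m/s).
#' @param vp Particle velocity, same shape (m/s).
#' @return Force in newtons.
#' @export
drag_force <- function(particle, fluid, u_fluid, vp) {
  stopifnot(inherits(particle, "particle_spec"), inherits(fluid, "fluid_spec"))
  6 * pi * fluid$viscosity * (particle$diameter / 2) * (u_fluid - vp)
}

#' Overdamped particle velocity
#'
#' Force balance of magnetophoresis against Stokes drag:
#' `vp = u + Fmap / (6 pi eta r)`.  The magnetophoretic slip scales as `D^2`
#' (force `D^3` over drag `D`), which is why larger MNPs trap better.
#'
#' @inheritParams magnetophoretic_force
#' @param u_fluid Fluid velocity, length-3 vector or n x 3 matrix (m/s).
#' @return Particle velocity (m/s), same shape as the inputs.
#' @export
slip_velocity <- function(particle, fluid, gradH2, u_fluid) {
  f <- magnetophoretic_force(particle, fluid, gradH2)
  u_fluid + f / (6 * pi * fluid$viscosity * particle$diameter / 2)
}

# slip mobility coefficient: vp - u = .slip_coef * gradH2
.slip_coef <- function(particle, fluid) {
  mur <- fluid$rel_permeability
  murp <- particle$rel_permeability
  cm <- (murp - mur) / (murp + 2 * mur)
  0.25 * pi * mur * .mu0 * particle$diameter^3 * cm /
    (6 * pi * fluid$viscosity * particle$diameter / 2)
}

# ---- gridded transport field ------------------------------------------------

# vectorized bilinear interpolation on a regular grid; x, y clamped to range
.interp2 <- function(x0, dx, nx, y0, dy, ny, Z, x, y) {
  fx <- pmin(pmax((x - x0) / dx, 0), nx - 1 - 1e-9)
  fy <- pmin(pmax((y - y0) / dy, 0), ny - 1 - 1e-9)
  ix <- floor(fx); iy <- floor(fy)
  tx <- fx - ix; ty <- fy - iy
  i11 <- ix + 1L + iy * nx
  z11 <- Z[i11]; z21 <- Z[i11 + 1L]
  z12 <- Z[i11 + nx]; z22 <- Z[i11 + nx + 1L]
  z11 * (1 - tx) * (1 - ty) + z21 * tx * (1 - ty) +
    z12 * (1 - tx) * ty + z22 * tx * ty
}

# Build (and cache) the gridded field used by the ensemble integrator:
# |H|^2 of the coil on a (rho, z) grid at 1 um spacing, its central-difference
# gradient, and the duct velocity on a (y, z) grid.  The spiral field is
# axisymmetric (feed lines are not part of the transport model), so a 2D
# grid suffices.
.transport_field <- function(config) {
  coil <- config$coil; ch <- config$channel
  d <- 1e-6  # grid spacing = central-difference step

  # coil-field part: depends only on coil geometry/current, channel box and
  # the quadrature flag
  fkey <- .config_hash(list("field",
                            coil[c("outer_radius", "n_turns", "wire_width",
                                   "wire_height", "spacing", "current")],
                            ch[c("width", "height", "coil_separation",
                                 "lateral_offset")],
                            config$sim$quadrature, config$sim$n_sub))
  fpart <- get0(fkey, envir = .magsense_cache)
  if (is.null(fpart)) {
    x_half <- 1.2 * coil$outer_radius
    rho_max <- sqrt(x_half^2 + (abs(ch$lateral_offset) + ch$width / 2)^2) + 5e-6
    z_lo <- ch$coil_separation - d
    z_hi <- ch$coil_separation + ch$height + d
    rho <- seq(0, rho_max, by = d)
    zz <- seq(z_lo, z_hi, by = d)
    pts <- cbind(rep(rho, times = length(zz)), 0, rep(zz, each = length(rho)))
    B <- .coil_B(coil, pts, quadrature = config$sim$quadrature,
                 n_sub = config$sim$n_sub)
    H2 <- matrix((B[, 1]^2 + B[, 2]^2 + B[, 3]^2) / .mu0^2,
                 nrow = length(rho), ncol = length(zz))
    nr <- length(rho); nz <- length(zz)
    # central differences on the grid interior; one-sided at the edges
    dH2drho <- (H2[c(2:nr, nr), ] - H2[c(1, 1:(nr - 1)), ]) /
      ((c(2:nr, nr) - c(1, 1:(nr - 1))) * d)
    dH2dz <- (H2[, c(2:nz, nz)] - H2[, c(1, 1:(nz - 1))]) /
      rep((c(2:nz, nz) - c(1, 1:(nz - 1))) * d, each = nr)
    fpart <- list(rho0 = 0, drho = d, nrho = nr, z0 = z_lo, dz = d, nz = nz,
                  dH2drho = dH2drho, dH2dz = dH2dz, x_half = x_half)
    assign(fkey, fpart, envir = .magsense_cache)
  }

  # flow part: depends only on channel and fluid
  wkey <- .config_hash(list("flow",
                            ch[c("width", "height", "coil_separation",
                                 "lateral_offset")],
                            config$fluid, config$sim$series_terms))
  wpart <- get0(wkey, envir = .magsense_cache)
  if (is.null(wpart)) {
    flow <- solve_flow(ch, config$fluid, config$sim$series_terms)
    ny_g <- max(21L, ceiling(ch$width / d) + 1L)
    nzc <- max(21L, ceiling(ch$height / d) + 1L)
    yg <- seq(-ch$width / 2, ch$width / 2, length.out = ny_g)
    zg <- seq(0, ch$height, length.out = nzc)
    U <- outer(yg, zg, function(y, z)
      flow$scale * .duct_shape(y, z, ch$width, ch$height, flow$series_terms))
    wpart <- list(y0 = yg[1], dy = yg[2] - yg[1], ny = ny_g,
                  zc0 = 0, dzc = zg[2] - zg[1], nzc = nzc, U = U, flow = flow)
    assign(wkey, wpart, envir = .magsense_cache)
  }
  c(fpart, wpart)
}

# particle velocities at positions (n x 3) from the gridded field
.ensemble_velocity <- function(pos, fg, ch, scoef) {
  rho <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  gr <- .interp2(fg$rho0, fg$drho, fg$nrho, fg$z0, fg$dz, fg$nz,
                 fg$dH2drho, rho, pos[, 3])
  gz <- .interp2(fg$rho0, fg$drho, fg$nrho, fg$z0, fg$dz, fg$nz,
                 fg$dH2dz, rho, pos[, 3])
  inv <- ifelse(rho > 1e-12, 1 / rho, 0)
  u <- .interp2(fg$y0, fg$dy, fg$ny, fg$zc0, fg$dzc, fg$nzc, fg$U,
                pos[, 2] - ch$lateral_offset, pos[, 3] - ch$coil_separation)
  cbind(u + scoef * gr * pos[, 1] * inv,
        scoef * gr * pos[, 2] * inv,
        scoef * gz)
}

# Cash-Karp RK45 tableau
.ck_a <- c(0, 1/5, 3/10, 3/5, 1, 7/8)
.ck_b <- list(
  numeric(0),
  c(1/5),
  c(3/40, 9/40),
  c(3/10, -9/10, 6/5),
  c(-11/54, 5/2, -70/27, 35/27),
  c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096))
.ck_c5 <- c(37/378, 0, 250/621, 125/594, 0, 512/1771)
.ck_c4 <- c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4)

#' Simulate an ensemble of MNPs through the device
#'
#' Particles are injected continuously over the first `inject_time` seconds
#' at the channel inlet (`x = -1.2 * outer_radius`), with inlet positions
#' sampled flux-weighted over the cross-section, and advected by adaptive
#' Cash-Karp Runge-Kutta integration of the overdamped velocity
#' `dx/dt = u + Fmap/(6 pi eta r)` on a gridded field (1 um spacing,
#' bilinear interpolation).  A particle is **trapped** when it comes within
#' one particle radius of the channel floor or a side wall while the
#' wall-normal magnetophoretic component points into the wall and its local
#' advection speed is below 1% of the mean flow; trapped particles are
#' frozen.  A particle that leaves the domain (`x > 1.2 * outer_radius`) has
#' **escaped**.  The run is deterministic given `(config, n_particles, seed)`.
#'
#' @param config A [device_config()].
#' @param n_particles Ensemble size; defaults to the config's.
#' @param seed RNG seed; defaults to the config's.
#' @return A `trap_result` with elements `particles` (per-particle outcome
#'   table), `bins` (1 s counts of injected/trapped/escaped/flowing),
#'   `efficiency` (percent at the horizon), `horizon`, `seed`,
#'   `config_hash`.
#' @export
simulate_ensemble <- function(config, n_particles = config$sim$n_particles,
                              seed = config$sim$seed) {
  stopifnot(inherits(config, "device_config"))
  n_particles <- .check_count(n_particles, "n_particles")
  seed <- .check_count(seed, "seed")
  sim <- config$sim; ch <- config$channel
  r <- config$particle$diameter / 2
  fg <- .transport_field(config)
  flow <- fg$flow
  scoef <- .slip_coef(config$particle, config$fluid)
  umean <- flow$mean_velocity
  speed_tol <- 0.01 * umean

  inlet <- sample_inlet(ch, flow, n_particles, seed,
                        weighting = "flux", clearance = r)
  t_inj <- (seq_len(n_particles) - 0.5) / n_particles * sim$inject_time
  # local integration horizon per particle
  t_end <- pmax(sim$horizon - t_inj, 0)

  x_min <- -fg$x_half; x_max <- fg$x_half
  z_floor <- ch$coil_separation + r
  z_ceil <- ch$coil_separation + ch$height - r
  y_lo <- ch$lateral_offset - ch$width / 2 + r
  y_hi <- ch$lateral_offset + ch$width / 2 - r

  pos <- cbind(x_min, inlet$y, inlet$z)
  tloc <- numeric(n_particles)
  dt <- rep(min(sim$dt_max, sim$step_length / max(umean, 1e-12)), n_particles)
  status <- rep("flowing", n_particles)
  t_event <- rep(NA_real_, n_particles)
  active <- rep(TRUE, n_particles)
  atol <- 1e-9

  vel <- function(p) .ensemble_velocity(p, fg, ch, scoef)

  max_iter <- 2e5L
  iter <- 0L
  while (any(active) && iter < max_iter) {
    iter <- iter + 1L
    idx <- which(active)
    p <- pos[idx, , drop = FALSE]
    h <- pmin(dt[idx], t_end[idx] - tloc[idx])
    h <- pmax(h, sim$dt_min)
    k1 <- vel(p)
    # displacement cap keeps the step within ~one grid cell
    spd <- sqrt(rowSums(k1^2))
    h <- pmin(h, ifelse(spd > 0, sim$step_length / spd, sim$dt_max),
              sim$dt_max)
    h <- pmax(pmin(h, t_end[idx] - tloc[idx]), sim$dt_min)
    k2 <- vel(p + h * .ck_b[[2]][1] * k1)
    k3 <- vel(p + h * (.ck_b[[3]][1] * k1 + .ck_b[[3]][2] * k2))
    k4 <- vel(p + h * (.ck_b[[4]][1] * k1 + .ck_b[[4]][2] * k2 +
                         .ck_b[[4]][3] * k3))
    k5 <- vel(p + h * (.ck_b[[5]][1] * k1 + .ck_b[[5]][2] * k2 +
                         .ck_b[[5]][3] * k3 + .ck_b[[5]][4] * k4))
    k6 <- vel(p + h * (.ck_b[[6]][1] * k1 + .ck_b[[6]][2] * k2 +
                         .ck_b[[6]][3] * k3 + .ck_b[[6]][4] * k4 +
                         .ck_b[[6]][5] * k5))
    p5 <- p + h * (.ck_c5[1] * k1 + .ck_c5[3] * k3 + .ck_c5[4] * k4 +
                     .ck_c5[6] * k6)
    p4 <- p + h * (.ck_c4[1] * k1 + .ck_c4[3] * k3 + .ck_c4[4] * k4 +
                     .ck_c4[5] * k5 + .ck_c4[6] * k6)
    err <- sqrt(rowSums((p5 - p4)^2)) /
      (atol + sim$rel_tol * pmax(sqrt(rowSums(p5^2)), 1e-6))
    accept <- err <= 1 | h <= sim$dt_min * 1.0001
    fac <- 0.9 * pmin(pmax(ifelse(err > 0, err^(-0.2), 5), 0.2), 5)
    dt[idx] <- pmin(pmax(h * fac, sim$dt_min), sim$dt_max)

    ai <- idx[accept]
    if (length(ai)) {
      pn <- p5[accept, , drop = FALSE]
      hn <- h[accept]
      tloc[ai] <- tloc[ai] + hn
      # wall handling at the new positions
      vz <- k6[accept, 3]          # end-of-step velocity components
      vy <- k6[accept, 2]
      spd_new <- sqrt(rowSums(k6[accept, , drop = FALSE]^2))
      at_floor <- pn[, 3] <= z_floor
      at_left <- pn[, 2] <= y_lo
      at_right <- pn[, 2] >= y_hi
      slow <- spd_new < speed_tol
      trap <- (at_floor & vz < 0 & slow) |
        (at_left & vy < 0 & slow) | (at_right & vy > 0 & slow)
      pn[, 3] <- pmin(pmax(pn[, 3], z_floor), z_ceil)
      pn[, 2] <- pmin(pmax(pn[, 2], y_lo), y_hi)
      esc <- pn[, 1] >= x_max & !trap
      done_time <- tloc[ai] >= t_end[ai] - 1e-12
      pos[ai, ] <- pn
      ti <- ai[trap]
      if (length(ti)) {
        status[ti] <- "trapped"; t_event[ti] <- t_inj[ti] + tloc[ti]
        active[ti] <- FALSE
      }
      ei <- ai[esc & !trap]
      if (length(ei)) {
        status[ei] <- "escaped"; t_event[ei] <- t_inj[ei] + tloc[ei]
        active[ei] <- FALSE
      }
      fi <- ai[done_time & !trap & !esc]
      if (length(fi)) active[fi] <- FALSE  # still flowing at the horizon
    }
  }
  if (iter >= max_iter)
    warning(sprintf("integrator hit the iteration cap; %d particle(s) left flowing",
                    sum(active)), call. = FALSE)

  particles <- data.frame(
    id = seq_len(n_particles), y0 = inlet$y, z0 = inlet$z, t_inject = t_inj,
    status = status, t_event = t_event,
    x = pos[, 1], y = pos[, 2], z = pos[, 3])
  tb <- 0:ceiling(sim$horizon)
  bins <- data.frame(
    t = tb,
    injected = vapply(tb, function(s) sum(t_inj <= s), numeric(1)),
    trapped = vapply(tb, function(s)
      sum(status == "trapped" & t_event <= s), numeric(1)),
    escaped = vapply(tb, function(s)
      sum(status == "escaped" & t_event <= s), numeric(1)))
  bins$flowing <- bins$injected - bins$trapped - bins$escaped
  structure(list(particles = particles, bins = bins,
                 efficiency = 100 * sum(status == "trapped") / n_particles,
                 horizon = sim$horizon, n = n_particles, seed = seed,
                 config_hash = .config_hash(config)),
            class = "trap_result")
}

#' @export
print.trap_result <- function(x, ...) {
  s <- table(factor(x$particles$status,
                    levels = c("trapped", "escaped", "flowing")))
  cat(sprintf("<trap_result> n = %d, seed = %d, horizon = %.0f s: %d trapped (%.1f%%), %d escaped, %d flowing\n",
              x$n, x$seed, x$horizon, s[["trapped"]], x$efficiency,
              s[["escaped"]], s[["flowing"]]))
  invisible(x)
}

#' Trapping efficiency of one or several ensemble runs
#'
#' `100 * trapped(t) / injected(t)`.  Given a list of runs (replicate
#' seeds), returns the across-seed mean with standard deviation in
#' `attr(, "sd")`.
#'
#' @param result A `trap_result` or a list of them.
#' @param t Evaluation time (s); defaults to the horizon.
#' @return Efficiency in percent.
#' @export
trapping_efficiency <- function(result, t = NULL) {
  if (inherits(result, "trap_result")) result <- list(result)
  stopifnot(all(vapply(result, inherits, logical(1), "trap_result")))
  effs <- vapply(result, function(res) {
    tt <- if (is.null(t)) res$horizon else t
    if (tt > res$horizon) stop("'t' exceeds the simulated horizon", call. = FALSE)
    p <- res$particles
    inj <- sum(p$t_inject <= tt)
    if (inj == 0) stop("'t' precedes the first injection", call. = FALSE)
    100 * sum(p$status == "trapped" & p$t_event <= tt) / inj
  }, numeric(1))
  structure(mean(effs), sd = if (length(effs) > 1) stats::sd(effs) else NA_real_)
}

#' Time to the steady-state trapping regime
#'
#' The resolved-trapping fraction `f(t) = trapped(t) / (trapped(t) +
#' escaped(t))` is evaluated on a 1 s grid; the steady-state time is the
#' earliest grid time after which `f` stays within `tol_pp` percentage
#' points of its final value.
#'
#' @param result A `trap_result` with horizon >= 20 s.
#' @param tol_pp Stability band (percentage points).
#' @return Time in seconds, or `NA` (with a `"reason"` attribute) when the
#'   fraction never stabilizes.
#' @export
time_to_steady_state <- function(result, tol_pp = 2) {
  stopifnot(inherits(result, "trap_result"))
  if (result$horizon < 20)
    stop("steady-state detection requires a horizon of at least 20 s",
         call. = FALSE)
  b <- result$bins
  resolved <- b$trapped + b$escaped
  f <- ifelse(resolved > 0, 100 * b$trapped / resolved, NA_real_)
  ok <- which(!is.na(f))
  if (!length(ok))
    return(structure(NA_real_, reason = "no particle resolved"))
  f_final <- f[max(ok)]
  within <- abs(f - f_final) <= tol_pp
  within[is.na(within)] <- TRUE   # unresolved early bins do not break stability
  # earliest index from which all later bins stay inside the band
  stable_from <- NA_integer_
  run <- rev(cumprod(rev(within)))
  cand <- which(run == 1)
  if (length(cand)) stable_from <- min(cand)
  first_resolved <- min(ok)
  if (is.na(stable_from))
    return(structure(NA_real_, reason = "never stabilizes",
                     fraction = f))
  b$t[max(stable_from, first_resolved)]
}

#' Single-particle trajectory (overdamped or inertial)
#'
#' Integrates one particle from `start` with the field evaluated directly
#' (elliptic-integral coil field, central-difference gradient) rather than
#' from the transport grid.  The inertial mode carries the particle mass and
#' serves as the stiff cross-check oracle for the overdamped reduction.
#'
#' @param config A [device_config()].
#' @param start Starting position `c(x, y, z)` (m).
#' @param t_max Integration time (s).
#' @param inertial Logical; integrate the full mass-carrying system.
#' @param n_out Number of output times.
#' @return A data frame with columns `t, x, y, z`.
#' @export
particle_trajectory <- function(config, start, t_max, inertial = FALSE,
                                n_out = 101L) {
  stopifnot(inherits(config, "device_config"))
  start <- as.numeric(start)
  flow <- solve_flow(config$channel, config$fluid, config$sim$series_terms)
  scoef <- .slip_coef(config$particle, config$fluid)
  times <- seq(0, t_max, length.out = n_out)
  vfun <- function(p) {
    g <- grad_H2(config$coil, matrix(p, 1L))
    u <- velocity_at(flow, matrix(p, 1L))
    as.numeric(u) + scoef * as.numeric(g)
  }
  if (!inertial) {
    sol <- deSolve::lsoda(
      y = start, times = times,
      func = function(t, y, parms) list(vfun(y)),
      rtol = 1e-8, atol = 1e-12)
    out <- as.data.frame(sol)
    names(out) <- c("t", "x", "y", "z")
    return(out)
  }
  m <- config$particle$mass_density * pi / 6 * config$particle$diameter^3
  gamma <- 6 * pi * config$fluid$viscosity * config$particle$diameter / 2
  v0 <- vfun(start)
  sol <- deSolve::lsoda(
    y = c(start, v0), times = times,
    func = function(t, y, parms) {
      p <- y[1:3]; v <- y[4:6]
      g <- grad_H2(config$coil, matrix(p, 1L))
      u <- velocity_at(flow, matrix(p, 1L))
      f <- magnetophoretic_force(config$particle, config$fluid,
                                 as.numeric(g)) +
        gamma * (as.numeric(u) - v)
      list(c(v, f / m))
    },
    rtol = 1e-8, atol = 1e-12)
  out <- as.data.frame(sol)[, 1:4]
  names(out) <- c("t", "x", "y", "z")
  out
}
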