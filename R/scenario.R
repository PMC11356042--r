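# Seeded scenario generation: inlet ensembles, randomized in-range device
# configurations, and analytically constructed trap results for oracle
# testing of the outcome statistics.

#' Sample particle inlet positions on the channel cross-section
#'
#' Positions are interior points of the inlet cross-section with at least
#' `clearance` to every wall.  `"flux"` weighting samples proportionally to
#' the local axial velocity (matching steady perfusion); `"uniform"` samples
#' the admissible rectangle uniformly.  Reproducible by seed; the caller's
#' RNG state is left untouched.
#'
#' @param channel A [channel_spec()].
#' @param flow A [solve_flow()] result for that channel.
#' @param n Number of particles.
#' @param seed RNG seed.
#' @param weighting `"flux"` or `"uniform"`.
#' @param clearance Minimal wall distance (m), normally one particle radius.
#' @return A data frame with columns `y`, `z` in device coordinates (m).
#' @export
sample_inlet <- function(channel, flow, n, seed,
                         weighting = c("flux", "uniform"),
                         clearance = 0) {
  stopifnot(inherits(channel, "channel_spec"), inherits(flow, "flow_field"))
  n <- .check_count(n, "n")
  weighting <- match.arg(weighting)
  .check_nonnegative(clearance, "clearance")
  b <- channel$width / 2 - clearance
  z_lo <- clearance; z_hi <- channel$height - clearance
  if (b <= 0 || z_hi <= z_lo)
    stop("clearance leaves no admissible inlet cross-section", call. = FALSE)
  umax <- flow$max_velocity
  .with_seed(seed, {
    ys <- numeric(0); zs <- numeric(0)
    while (length(ys) < n) {
      m <- max(2L * (n - length(ys)), 16L)
      y <- stats::runif(m, -b, b)
      z <- stats::runif(m, z_lo, z_hi)
      if (weighting == "flux") {
        u <- flow$scale * .duct_shape(y, z, channel$width, channel$height,
                                      flow$series_terms)
        keep <- stats::runif(m) < u / umax
        y <- y[keep]; z <- z[keep]
      }
      ys <- c(ys, y); zs <- c(zs, z)
    }
    data.frame(y = ys[seq_len(n)] + channel$lateral_offset,
               z = zs[seq_len(n)] + channel$coil_separation)
  })
}

#' Random in-range device configuration
#'
#' Draws a valid [device_config()] uniformly inside the design ranges
#' (coil current 100-700 mA, particle diameter 10-60 nm, coil-channel
#' separation 5-100 um, channel width 50-1000 um, electrode height
#' 20-500 um) with the coil picked uniformly from the four reference
#' layouts.
#'
#' @param seed RNG seed.
#' @param ranges Optional named list overriding individual ranges; each
#'   element is `c(lo, hi)` in SI units: `current` (A), `diameter` (m),
#'   `coil_separation` (m), `width` (m), `electrode_height` (m).
#' @return A [device_config()].
#' @export
random_device <- function(seed, ranges = list()) {
  seed <- .check_count(seed, "seed")
  def <- list(current = c(0.1, 0.7), diameter = c(10e-9, 60e-9),
              coil_separation = c(5e-6, 100e-6), width = c(50e-6, 1000e-6),
              electrode_height = c(20e-6, 500e-6))
  bad <- setdiff(names(ranges), names(def))
  if (length(bad))
    stop(sprintf("unknown range name(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (!is.numeric(rg) || length(rg) != 2L || any(!is.finite(rg)) ||
        rg[2] < rg[1] || rg[1] <= 0)
      stop(sprintf("range '%s' must be a valid positive c(lo, hi)", nm),
           call. = FALSE)
    def[[nm]] <- rg
  }
  .with_seed(seed, {
    coil_name <- sample(names(.coil_catalog), 1L)
    draw <- function(rg) stats::runif(1L, rg[1], rg[2])
    base <- suppressWarnings(default_device_config(coil_name))
    coil <- suppressWarnings(coil_spec(
      outer_radius = base$coil$outer_radius, n_turns = base$coil$n_turns,
      current = draw(def$current), name = coil_name))
    width <- draw(def$width)
    channel <- channel_spec(width = width, height = base$channel$height,
                            length = base$channel$length,
                            coil_separation = draw(def$coil_separation))
    particle <- particle_spec(diameter = draw(def$diameter))
    stack <- dielectric_stack(channel_thickness = width,
                              eps_channel = base$fluid$rel_permittivity)
    electrodes <- electrode_spec(
      height = draw(def$electrode_height),
      gap = width + 2 * stack$wall_thickness)
    device_config(coil = coil, channel = channel, fluid = base$fluid,
                  particle = particle, electrodes = electrodes,
                  stack = stack, sim = base$sim)
  })
}

#' Analytically constructed trap result
#'
#' Builds a `trap_result` with known outcome statistics, for oracle-testing
#' [trapping_efficiency()] and [time_to_steady_state()] without running the
#' integrator.
#'
#' * `"constant-rate"`: particles resolve a fixed time after injection with
#'   a constant trapped fraction, so the efficiency at the horizon is
#'   exactly `efficiency`.
#' * `"step"`: the trapped fraction switches from `efficiency_early` to
#'   `efficiency` for particles resolving after `change_point` seconds.
#' * `"none-trapped"`: every particle escapes.
#'
#' @param pattern One of `"constant-rate"`, `"step"`, `"none-trapped"`.
#' @param n Number of particles (a multiple of 100 keeps the fractions
#'   exact).
#' @param horizon Result horizon (s).
#' @param inject_time Injection window (s).
#' @param resolve_delay Time from injection to outcome (s).
#' @param efficiency Trapped percentage (final regime for `"step"`).
#' @param efficiency_early Trapped percentage before `change_point`
#'   (`"step"` only).
#' @param change_point Absolute time of the rate switch (s, `"step"` only).
#' @return A `trap_result`.
#' @export
fixture_trap_result <- function(pattern = c("constant-rate", "step",
                                            "none-trapped"),
                                n = 100L, horizon = 60, inject_time = 10,
                                resolve_delay = 0.5, efficiency = 80,
                                efficiency_early = 20, change_point = 20) {
  pattern <- match.arg(pattern)
  n <- .check_count(n, "n")
  t_inj <- (seq_len(n) - 0.5) / n * inject_time
  t_event <- t_inj + resolve_delay
  frac <- switch(pattern,
    "none-trapped" = rep(0, n),
    "constant-rate" = rep(efficiency / 100, n),
    "step" = ifelse(t_event < change_point, efficiency_early / 100,
                    efficiency / 100))
  # deterministic assignment keeping every prefix fraction exact:
  # particle i is trapped iff floor(i * frac) > floor((i-1) * frac)
  cum <- floor(seq_len(n) * frac + 1e-9)
  status <- ifelse(diff(c(0, cum)) > 0, "trapped", "escaped")
  particles <- data.frame(
    id = seq_len(n), y0 = 0, z0 = 0, t_inject = t_inj,
    status = status, t_event = t_event, x = 0, y = 0, z = 0)
  tb <- 0:ceiling(horizon)
  bins <- data.frame(
    t = tb,
    injected = vapply(tb, function(s) sum(t_inj <= s), numeric(1)),
    trapped = vapply(tb, function(s)
      sum(status == "trapped" & t_event <= s), numeric(1)),
    escaped = vapply(tb, function(s)
      sum(status == "escaped" & t_event <= s), numeric(1)))
  bins$flowing <- bins$injected - bins$trapped - bins$escaped
  structure(list(particles = particles, bins = bins,
                 efficiency = 100 * mean(status == "trapped"),
                 horizon = horizon, n = n, seed = NA_integer_,
                 config_hash = sprintf("fixture-%s", pattern)),
            class = "trap_result")
}
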