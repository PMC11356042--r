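# Direct-field capacitive readout.
#
# The detection zone is a parallel-plate capacitor whose dielectric is a
# PDMS wall / fluid channel / PDMS wall series stack.  Trapped MNPs lower
# the effective permittivity of the channel layer; the occupancy model
# treats the MNP-rich plug as a column spanning the full gap over a length
# fraction phi of the electrodes ("parallel-column"), with a homogeneous
# linear mixture and a Maxwell-Garnett mixing rule as alternatives.
# Electrodes are ideal conductors: material conductivity is metadata only.

#' Parallel-plate capacitance
#'
#' `C = eps0 * eps_r * A / d` with `A = height * length` and `d` the plate
#' separation.
#'
#' @param electrodes An [electrode_spec()].
#' @param eps_r Relative permittivity of the medium between the plates.
#' @return Capacitance (farad).
#' @export
#' @examples
#' el <- electrode_spec(height = 50e-6, length = 500e-6, gap = 50e-6)
#' parallel_plate_capacitance(el, 80) * 1e15  # 354.2 fF
parallel_plate_capacitance <- function(electrodes, eps_r) {
  stopifnot(inherits(electrodes, "electrode_spec"))
  .check_positive(eps_r, "eps_r")
  .eps0 * eps_r * electrodes$area / electrodes$gap
}

#' Series-stack capacitance of the detection zone
#'
#' Equivalent capacitance of the PDMS-channel-PDMS series stack,
#' `Ceq = eps0 * A * eps_w * eps_ch / (eps_w * d_ch + 2 * eps_ch * d_w)`,
#' i.e. the harmonic combination of the three parallel-plate layers.  With
#' zero wall thickness it reduces exactly to the single-layer formula.
#'
#' @param electrodes An [electrode_spec()].
#' @param stack A [dielectric_stack()].
#' @param eps_channel Optional override of the channel-layer permittivity
#'   (used by the mixing models).
#' @return Capacitance (farad).
#' @export
stack_capacitance <- function(electrodes, stack,
                              eps_channel = stack$eps_channel) {
  stopifnot(inherits(electrodes, "electrode_spec"),
            inherits(stack, "dielectric_stack"))
  .check_positive(eps_channel, "eps_channel")
  .eps0 * electrodes$area * stack$eps_wall * eps_channel /
    (stack$eps_wall * stack$channel_thickness +
       2 * eps_channel * stack$wall_thickness)
}

#' MNP occupancy state of the detection zone
#'
#' @param phi Fraction of the detection-zone channel volume filled by the
#'   MNP-rich phase, in `[0, 1]`.
#' @param eps_p Relative permittivity of the MNP phase (10-40 for iron
#'   oxides).
#' @param model Occupancy geometry: `"parallel-column"` (an MNP plug spans
#'   the full gap over a length fraction `phi` of the electrodes),
#'   `"linear-mixture"` (volume-weighted permittivity), or
#'   `"maxwell-garnett"` (spherical-inclusion mixing rule).
#' @return An object of class `occupancy_state`.
#' @export
occupancy_state <- function(phi, eps_p = 10,
                            model = c("parallel-column", "linear-mixture",
                                      "maxwell-garnett")) {
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) ||
      phi < 0 || phi > 1)
    stop("'phi' must be a single number in [0, 1]", call. = FALSE)
  .check_positive(eps_p, "eps_p")
  model <- match.arg(model)
  structure(list(phi = phi, eps_p = eps_p, model = model),
            class = "occupancy_state")
}

# effective channel permittivity of the homogeneous mixing models
.mix_eps <- function(phi, eps_ch, eps_p, model) {
  switch(model,
    "linear-mixture" = (1 - phi) * eps_ch + phi * eps_p,
    "maxwell-garnett" = {
      num <- eps_p + 2 * eps_ch + 2 * phi * (eps_p - eps_ch)
      den <- eps_p + 2 * eps_ch - phi * (eps_p - eps_ch)
      eps_ch * num / den
    },
    stop(sprintf("unknown mixing model '%s'", model), call. = FALSE))
}

#' Detection-zone capacitance at a given MNP occupancy
#'
#' Under the default parallel-column geometry,
#' `C(phi) = (1 - phi) * Cstack(eps_ch) + phi * Cstack(eps_p)` -- affine in
#' `phi`.  The mixing models instead replace the channel permittivity by a
#' phi-weighted effective value inside the series stack.
#'
#' @param electrodes An [electrode_spec()].
#' @param stack A [dielectric_stack()].
#' @param occ An [occupancy_state()].
#' @return Capacitance (farad).
#' @export
occupancy_capacitance <- function(electrodes, stack, occ) {
  stopifnot(inherits(occ, "occupancy_state"))
  if (occ$model == "parallel-column") {
    (1 - occ$phi) * stack_capacitance(electrodes, stack) +
      occ$phi * stack_capacitance(electrodes, stack, eps_channel = occ$eps_p)
  } else {
    eff <- .mix_eps(occ$phi, stack$eps_channel, occ$eps_p, occ$model)
    stack_capacitance(electrodes, stack, eps_channel = eff)
  }
}

#' Occupancy sensitivity of the readout
#'
#' Relative capacitance change caused by the MNP occupancy:
#' `100 * (C(0) - C(phi)) / C(0)` in percent.  Positive when the MNP phase
#' has lower permittivity than the fluid.
#'
#' @inheritParams occupancy_capacitance
#' @return Sensitivity (percent).
#' @export
#' @examples
#' el <- electrode_spec(height = 50e-6, length = 500e-6, gap = 60e-6)
#' st <- dielectric_stack()
#' sensitivity(el, st, occupancy_state(0.85, eps_p = 10))  # ~42.7%
sensitivity <- function(electrodes, stack, occ) {
  c0 <- occupancy_capacitance(electrodes, stack,
                              occupancy_state(0, occ$eps_p, occ$model))
  cphi <- occupancy_capacitance(electrodes, stack, occ)
  100 * (c0 - cphi) / c0
}

#' Capacitance change between two states
#'
#' `delta_capacitance = C_after - C_before`; negative when the effective
#' permittivity drops (MNP accumulation).
#'
#' @param c_before,c_after Capacitances (farad).
#' @return `c_after - c_before` (farad).
#' @export
delta_capacitance <- function(c_before, c_after) c_after - c_before

#' Occupancy time series implied by a trapping run
#'
#' Converts trapped-particle counts into a detection-zone occupancy: each
#' simulated particle represents `mnp_concentration * Q * inject_time / n`
#' physical MNPs; the trapped MNP volume, divided by the plug packing
#' fraction, gives the MNP-rich plug volume, and `phi` is its fraction of
#' the detection-zone channel volume, clipped to `[0, 1]`.
#'
#' @param result A `trap_result` from [simulate_ensemble()].
#' @param config The [device_config()] the run used.
#' @param zone Detection-zone extent along the channel, `c(x_min, x_max)`
#'   (m); defaults to the electrode length centered on the coil.
#' @return A data frame with columns `t` (s) and `phi`.
#' @export
occupancy_from_trap <- function(result, config, zone = NULL) {
  stopifnot(inherits(result, "trap_result"), inherits(config, "device_config"))
  half_dom <- 1.2 * config$coil$outer_radius
  if (is.null(zone))
    zone <- c(-1, 1) * config$electrodes$length / 2
  if (zone[1] < -half_dom || zone[2] > half_dom)
    stop("detection zone extends outside the simulated domain", call. = FALSE)
  ch <- config$channel
  v_zone <- diff(zone) * ch$width * ch$height
  v_p <- pi / 6 * config$particle$diameter^3
  weight <- config$sim$mnp_concentration * config$fluid$flow_rate *
    config$sim$inject_time / result$n
  p <- result$particles
  in_zone <- p$status == "trapped" & p$x >= zone[1] & p$x <= zone[2]
  tb <- result$bins$t
  n_zone <- vapply(tb, function(s) sum(in_zone & p$t_event <= s), numeric(1))
  phi <- pmin(n_zone * weight * v_p / config$sim$packing_fraction / v_zone, 1)
  data.frame(t = tb, phi = phi)
}

#' Dynamic capacitance trace under a coil on/off schedule
#'
#' Couples the trapping simulation to the occupancy readout: while the coil
#' is on, trapped MNPs accumulate in the detection zone and depress the
#' capacitance; switching the coil off releases the plug, which is washed
#' out advectively (exponential decay with time constant
#' `zone length / mean velocity`), returning the trace to baseline.  Without
#' Brownian re-entrainment a released particle in the zero-velocity wall
#' layer would linger unphysically, so release is modelled at the occupancy
#' level rather than by re-integrating near-wall particles.
#'
#' @param config A [device_config()].
#' @param schedule Data frame with columns `start`, `end`: coil-on
#'   intervals (s).  An empty schedule keeps the coil off.
#' @param n_particles,seed Ensemble controls, defaulting to the config's.
#' @return A data frame with columns `t` (s), `phi`, `C` (farad).
#' @export
dynamic_trace <- function(config, schedule, n_particles = config$sim$n_particles,
                          seed = config$sim$seed) {
  stopifnot(inherits(config, "device_config"), is.data.frame(schedule) ||
              is.null(schedule))
  horizon <- config$sim$horizon
  tb <- seq(0, horizon, by = 0.25)
  if (is.null(schedule) || nrow(schedule) == 0L) {
    phi <- rep(0, length(tb))
  } else {
    if (any(schedule$end <= schedule$start) || any(schedule$start < 0) ||
        any(schedule$end > horizon))
      stop("schedule intervals must satisfy 0 <= start < end <= horizon",
           call. = FALSE)
    res <- simulate_ensemble(config, n_particles, seed)
    occ <- occupancy_from_trap(res, config)
    p <- res$particles
    zone <- c(-1, 1) * config$electrodes$length / 2
    flow <- solve_flow(config$channel, config$fluid, config$sim$series_terms)
    tau <- diff(zone) / flow$mean_velocity  # advective washout time
    on_at <- function(t) {
      hit <- schedule$start <= t & t < schedule$end
      any(hit)
    }
    in_zone <- p$status == "trapped" & p$x >= zone[1] & p$x <= zone[2]
    # trapping events count only while the coil is on; afterwards the
    # accumulated plug decays towards zero with time constant tau
    phi_of <- stats::approxfun(occ$t, occ$phi, rule = 2)
    phi <- numeric(length(tb))
    level <- 0
    prev_t <- 0
    prev_phi_on <- 0
    for (i in seq_along(tb)) {
      t <- tb[i]
      dt <- t - prev_t
      if (on_at(t)) {
        gain <- max(phi_of(t) - prev_phi_on, 0)
        level <- min(level + gain, 1)
        prev_phi_on <- phi_of(t)
      } else {
        level <- level * exp(-dt / tau)
        prev_phi_on <- phi_of(t)  # events while the coil is off do not count
      }
      phi[i] <- level
      prev_t <- t
    }
  }
  el <- config$electrodes; st <- config$stack
  eps_p <- config$particle$rel_permittivity
  C <- vapply(phi, function(f)
    occupancy_capacitance(el, st, occupancy_state(f, eps_p)), numeric(1))
  data.frame(t = tb, phi = phi, C = C)
}
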