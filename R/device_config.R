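#' Planar spiral coil specification
#'
#' Describes one planar spiral copper microcoil, modelled as `n_turns`
#' concentric circular filaments at pitch `wire_width + spacing`.  The axial
#' origin `z = 0` sits on the *top surface* of the wires, so the filament
#' centerlines lie at `z = -wire_height/2` and the microchannel floor at
#' `z = coil_separation`.
#'
#' @param outer_radius Outer radius of the outermost turn (m).
#' @param n_turns Number of turns (positive integer).
#' @param wire_width,wire_height Wire cross-section (m); 10 x 10 um by default.
#' @param spacing Gap between adjacent wires (m).
#' @param current Drive current (A).  Values outside the 0.1-0.7 A design
#'   range trigger a warning, never an error.
#' @param conductivity Wire conductivity (S/m); copper by default.
#' @param name Optional label (e.g. `"R2000"`).
#' @return An object of class `coil_spec`.
#' @seealso [derive_loop_set()], [default_device_config()]
#' @export
#' @examples
#' coil <- coil_spec(outer_radius = 500e-6, n_turns = 22)
#' derive_loop_set(coil)
coil_spec <- function(outer_radius, n_turns, wire_width = 10e-6,
                      wire_height = 10e-6, spacing = 10e-6, current = 0.4,
                      conductivity = 59.6e6, name = NULL) {
  .check_positive(outer_radius, "outer_radius")
  n_turns <- .check_count(n_turns, "n_turns")
  .check_positive(wire_width, "wire_width")
  .check_positive(wire_height, "wire_height")
  .check_nonnegative(spacing, "spacing")
  if (!is.numeric(current) || length(current) != 1L || !is.finite(current))
    stop("'current' must be a single finite number", call. = FALSE)
  .check_positive(conductivity, "conductivity")
  pitch <- wire_width + spacing
  if (pitch <= 0)
    stop("'wire_width' + 'spacing' (pitch) must be positive", call. = FALSE)
  inner <- outer_radius - wire_width / 2 - (n_turns - 1L) * pitch
  if (inner <= 0)
    stop(sprintf(
      "innermost filament radius is %.3g m (<= 0); reduce 'n_turns' (%d) or increase 'outer_radius'",
      inner, n_turns), call. = FALSE)
  if (is.finite(current) && (abs(current) < 0.1 - 1e-9 ||
                             abs(current) > 0.7 + 1e-9))
    warning(sprintf("coil current %.3g A lies outside the 0.1-0.7 A design range",
                    current), call. = FALSE)
  structure(list(outer_radius = outer_radius, n_turns = n_turns,
                 wire_width = wire_width, wire_height = wire_height,
                 spacing = spacing, current = current,
                 conductivity = conductivity,
                 name = if (is.null(name)) NA_character_ else as.character(name)),
            class = "coil_spec")
}

#' @export
print.coil_spec <- function(x, ...) {
  cat(sprintf("<coil_spec%s> outer radius %.0f um, %d turns, wire %.0fx%.0f um, pitch %.0f um, I = %.0f mA\n",
              if (is.na(x$name)) "" else paste0(" ", x$name),
              x$outer_radius * 1e6, x$n_turns, x$wire_width * 1e6,
              x$wire_height * 1e6, (x$wire_width + x$spacing) * 1e6,
              x$current * 1e3))
  invisible(x)
}

#' Microchannel specification
#'
#' @param width Channel width along the lateral `y` axis (m).
#' @param height Channel height along `z` (m).
#' @param length Channel length along the flow axis `x` (m).
#' @param coil_separation Vertical gap between the coil wire top surface and
#'   the channel floor (m); the floor sits at `z = coil_separation`.
#' @param lateral_offset Lateral offset of the channel axis from the coil
#'   center (m); 0 places the channel over the coil center.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(width, height, length, coil_separation,
                         lateral_offset = 0) {
  .check_positive(width, "width")
  .check_positive(height, "height")
  .check_positive(length, "length")
  .check_nonnegative(coil_separation, "coil_separation")
  if (!is.numeric(lateral_offset) || length(lateral_offset) != 1L ||
      !is.finite(lateral_offset))
    stop("'lateral_offset' must be a single finite number", call. = FALSE)
  structure(list(width = width, height = height, length = length,
                 coil_separation = coil_separation,
                 lateral_offset = lateral_offset),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel_spec> %.0f x %.0f um cross-section, length %.0f um, coil separation %.0f um\n",
              x$width * 1e6, x$height * 1e6, x$length * 1e6,
              x$coil_separation * 1e6))
  invisible(x)
}

#' Working fluid (sweat) specification
#'
#' @param density Mass density (kg/m^3).
#' @param viscosity Dynamic viscosity (Pa s).
#' @param flow_rate Volumetric flow rate (m^3/s); 1 uL/min = `1e-9/60`.
#' @param rel_permeability Relative magnetic permeability of the fluid
#'   (dimensionless, ~1 for water/sweat).
#' @param rel_permittivity Relative permittivity of the fluid (~80 for sweat).
#' @return An object of class `fluid_spec`.
#' @export
fluid_spec <- function(density = 1000, viscosity = 1e-3,
                       flow_rate = 1e-9 / 60, rel_permeability = 1,
                       rel_permittivity = 80) {
  .check_positive(density, "density")
  .check_positive(viscosity, "viscosity")
  .check_positive(flow_rate, "flow_rate")
  if (!is.numeric(rel_permeability) || rel_permeability < 1)
    stop("'rel_permeability' must be >= 1", call. = FALSE)
  .check_positive(rel_permittivity, "rel_permittivity")
  structure(list(density = density, viscosity = viscosity,
                 flow_rate = flow_rate, rel_permeability = rel_permeability,
                 rel_permittivity = rel_permittivity),
            class = "fluid_spec")
}

#' Magnetic nanoparticle specification
#'
#' @param diameter Particle diameter (m).
#' @param rel_permeability Relative magnetic permeability of the particle
#'   material (magnetite ~5000); enters the force only through the
#'   Clausius-Mossotti contrast factor.
#' @param rel_permittivity Relative permittivity of the particle material
#'   (10-40 for iron-oxide MNPs); used by the capacitive readout.
#' @param mass_density Particle mass density (kg/m^3); used only by the
#'   optional inertial integration mode.
#' @return An object of class `particle_spec`.
#' @export
particle_spec <- function(diameter, rel_permeability = 5000,
                          rel_permittivity = 10, mass_density = 5200) {
  .check_positive(diameter, "diameter")
  .check_positive(rel_permeability, "rel_permeability")
  .check_positive(rel_permittivity, "rel_permittivity")
  .check_positive(mass_density, "mass_density")
  structure(list(diameter = diameter, rel_permeability = rel_permeability,
                 rel_permittivity = rel_permittivity,
                 mass_density = mass_density),
            class = "particle_spec")
}

#' Parallel-plate electrode specification
#'
#' The two electrodes face each other across the channel width; their plate
#' separation (`gap`) spans the PDMS wall - channel - PDMS wall stack.
#' Electrode material enters only as metadata: capacitance assumes ideal
#' conductors.
#'
#' @param height Electrode height (m).
#' @param length Electrode length along the detection zone (m).
#' @param gap Plate separation (m).
#' @param conductivity Electrode material conductivity (S/m, metadata only).
#' @param voltage Drive voltage (V, metadata only).
#' @return An object of class `electrode_spec` with derived `area = height * length`.
#' @export
electrode_spec <- function(height = 50e-6, length = 500e-6, gap = 60e-6,
                           conductivity = 59.6e6, voltage = 5) {
  .check_positive(height, "height")
  .check_positive(length, "length")
  .check_positive(gap, "gap")
  .check_positive(conductivity, "conductivity")
  .check_positive(voltage, "voltage")
  structure(list(height = height, length = length, gap = gap,
                 area = height * length, conductivity = conductivity,
                 voltage = voltage),
            class = "electrode_spec")
}

#' Layered dielectric stack of the detection zone
#'
#' PDMS wall - fluid channel - PDMS wall in series between the electrode
#' plates; total plate separation is `channel_thickness + 2 * wall_thickness`.
#'
#' @param channel_thickness Fluid gap (m), equal to the channel width.
#' @param wall_thickness Thickness of each PDMS wall (m).
#' @param eps_channel Relative permittivity of the channel fluid.
#' @param eps_wall Relative permittivity of the PDMS wall (~2.7).
#' @return An object of class `dielectric_stack`.
#' @export
dielectric_stack <- function(channel_thickness = 50e-6, wall_thickness = 5e-6,
                             eps_channel = 80, eps_wall = 2.7) {
  .check_positive(channel_thickness, "channel_thickness")
  .check_nonnegative(wall_thickness, "wall_thickness")
  .check_positive(eps_channel, "eps_channel")
  .check_positive(eps_wall, "eps_wall")
  structure(list(channel_thickness = channel_thickness,
                 wall_thickness = wall_thickness,
                 eps_channel = eps_channel, eps_wall = eps_wall),
            class = "dielectric_stack")
}

#' Simulation controls
#'
#' @param horizon Simulated time horizon (s).
#' @param n_particles Ensemble size.
#' @param seed Base RNG seed.
#' @param inject_time Particles are injected continuously over the first
#'   `inject_time` seconds (s).
#' @param series_terms Number of odd Fourier terms for the duct-flow solution.
#' @param step_length Target spatial step of the particle integrator (m).
#' @param dt_max,dt_min Time-step bounds of the adaptive integrator (s).
#' @param rel_tol Relative error tolerance of the adaptive integrator.
#' @param quadrature Represent each wire cross-section by an
#'   `n_sub` x `n_sub` sub-filament grid (needed to resolve near-field ripple).
#' @param n_sub Sub-filament grid order per wire when `quadrature` is on.
#' @param mnp_concentration Physical MNP number concentration at the inlet
#'   (1/m^3); converts simulated counts to occupancy in the dynamic trace.
#' @param packing_fraction Volume fraction of MNPs inside a settled plug;
#'   converts trapped MNP volume to plug volume.
#' @return An object of class `sim_control`.
#' @export
sim_control <- function(horizon = 60, n_particles = 500, seed = 1L,
                        inject_time = 10, series_terms = 51,
                        step_length = 1e-6, dt_max = 0.05, dt_min = 1e-7,
                        rel_tol = 1e-6, quadrature = FALSE, n_sub = 3L,
                        mnp_concentration = 1e18, packing_fraction = 0.01) {
  .check_positive(horizon, "horizon")
  if (horizon > 600) stop("'horizon' must be <= 600 s", call. = FALSE)
  n_particles <- .check_count(n_particles, "n_particles")
  seed <- .check_count(seed, "seed")
  .check_positive(inject_time, "inject_time")
  series_terms <- .check_count(series_terms, "series_terms")
  if (series_terms < 11L || series_terms %% 2L == 0L)
    stop("'series_terms' must be an odd integer >= 11", call. = FALSE)
  .check_positive(step_length, "step_length")
  .check_positive(dt_max, "dt_max")
  .check_positive(dt_min, "dt_min")
  .check_positive(rel_tol, "rel_tol")
  n_sub <- .check_count(n_sub, "n_sub")
  .check_positive(mnp_concentration, "mnp_concentration")
  .check_positive(packing_fraction, "packing_fraction")
  if (packing_fraction > 1) stop("'packing_fraction' must be <= 1", call. = FALSE)
  structure(list(horizon = horizon, n_particles = n_particles, seed = seed,
                 inject_time = inject_time, series_terms = series_terms,
                 step_length = step_length, dt_max = dt_max, dt_min = dt_min,
                 rel_tol = rel_tol, quadrature = isTRUE(quadrature),
                 n_sub = n_sub, mnp_concentration = mnp_concentration,
                 packing_fraction = packing_fraction),
            class = "sim_control")
}

#' Full device configuration
#'
#' Bundles all component specifications and enforces the cross-component
#' invariants: the dielectric stack's fluid gap equals the channel width, and
#' the electrode plate separation equals fluid gap plus both PDMS walls.
#'
#' @param coil A [coil_spec()].
#' @param channel A [channel_spec()].
#' @param fluid A [fluid_spec()].
#' @param particle A [particle_spec()].
#' @param electrodes An [electrode_spec()], or `NULL` to derive one from the
#'   channel and stack geometry.
#' @param stack A [dielectric_stack()], or `NULL` to derive one from the
#'   channel width and fluid permittivity.
#' @param sim A [sim_control()].
#' @return An object of class `device_config`.
#' @export
device_config <- function(coil, channel, fluid, particle, electrodes = NULL,
                          stack = NULL, sim = sim_control()) {
  stopifnot(inherits(coil, "coil_spec"), inherits(channel, "channel_spec"),
            inherits(fluid, "fluid_spec"), inherits(particle, "particle_spec"),
            inherits(sim, "sim_control"))
  if (is.null(stack))
    stack <- dielectric_stack(channel_thickness = channel$width,
                              eps_channel = fluid$rel_permittivity)
  stopifnot(inherits(stack, "dielectric_stack"))
  if (is.null(electrodes))
    electrodes <- electrode_spec(gap = stack$channel_thickness +
                                   2 * stack$wall_thickness)
  stopifnot(inherits(electrodes, "electrode_spec"))
  if (abs(stack$channel_thickness - channel$width) > 1e-12)
    stop(sprintf(
      "stack 'channel_thickness' (%.3g m) must equal channel 'width' (%.3g m)",
      stack$channel_thickness, channel$width), call. = FALSE)
  gap_expected <- stack$channel_thickness + 2 * stack$wall_thickness
  if (abs(electrodes$gap - gap_expected) > 1e-12)
    stop(sprintf(
      "electrode 'gap' (%.3g m) must equal channel width + 2 PDMS walls (%.3g m)",
      electrodes$gap, gap_expected), call. = FALSE)
  if (particle$diameter >= channel$height / 2)
    stop("particle 'diameter' must be small compared to the channel height",
         call. = FALSE)
  structure(list(coil = coil, channel = channel, fluid = fluid,
                 particle = particle, electrodes = electrodes, stack = stack,
                 sim = sim),
            class = "device_config")
}

#' @export
print.device_config <- function(x, ...) {
  cat("<device_config>", if (!is.na(x$coil$name)) x$coil$name else "", "\n")
  print(x$coil); print(x$channel)
  cat(sprintf("  fluid: Q = %.3g uL/min, eta = %.3g Pa s, eps_r = %.3g\n",
              x$fluid$flow_rate * 6e10, x$fluid$viscosity,
              x$fluid$rel_permittivity))
  cat(sprintf("  particle: D = %.0f nm, mu_r = %.0f, eps_r = %.0f\n",
              x$particle$diameter * 1e9, x$particle$rel_permeability,
              x$particle$rel_permittivity))
  cat(sprintf("  electrodes: %.0f x %.0f um, gap %.0f um; stack walls %.0f um PDMS (eps %.2g)\n",
              x$electrodes$height * 1e6, x$electrodes$length * 1e6,
              x$electrodes$gap * 1e6, x$stack$wall_thickness * 1e6,
              x$stack$eps_wall))
  cat(sprintf("  sim: horizon %.0f s, %d particles, seed %d\n",
              x$sim$horizon, x$sim$n_particles, x$sim$seed))
  invisible(x)
}

# turn counts of the four reference coils: the innermost filament radius is
# fixed at 75 um (the value implied by the 97-turn R2000 coil at 20 um pitch)
# and turns fill outward to the nominal outer radius.
.coil_catalog <- list(
  R500  = list(outer_radius = 500e-6,  n_turns = 22L),
  R1000 = list(outer_radius = 1000e-6, n_turns = 47L),
  R1500 = list(outer_radius = 1500e-6, n_turns = 72L),
  R2000 = list(outer_radius = 2000e-6, n_turns = 97L))

#' Reference device configuration at the optimized operating point
#'
#' Returns the device at its optimized operating point: 50 x 50 um channel,
#' 30 um coil-channel separation, 50 nm MNPs, 1 uL/min sweat flow, 400 mA
#' drive, sweat permittivity 80, PDMS permittivity 2.7, copper wiring, and a
#' 50 x 500 um electrode pair with 5 um PDMS walls.
#'
#' @param coil_name One of `"R500"`, `"R1000"`, `"R1500"`, `"R2000"`.
#' @param ... Overrides forwarded to [sim_control()].
#' @return A [device_config()].
#' @export
#' @examples
#' cfg <- default_device_config("R2000")
#' cfg$coil$n_turns  # 97
default_device_config <- function(coil_name = c("R2000", "R1500", "R1000", "R500"),
                                  ...) {
  coil_name <- match.arg(coil_name)
  cat_entry <- .coil_catalog[[coil_name]]
  coil <- coil_spec(outer_radius = cat_entry$outer_radius,
                    n_turns = cat_entry$n_turns, current = 0.4,
                    name = coil_name)
  channel <- channel_spec(width = 50e-6, height = 50e-6,
                          length = 2.4 * coil$outer_radius,
                          coil_separation = 30e-6)
  fluid <- fluid_spec()
  particle <- particle_spec(diameter = 50e-9)
  device_config(coil = coil, channel = channel, fluid = fluid,
                particle = particle, sim = sim_control(...))
}

#' Filament layout of a spiral coil
#'
#' Discretizes the spiral into concentric circular filaments: radii
#' `r_k = outer_radius - wire_width/2 - k * pitch`, `k = 0..n_turns-1`, all in
#' the plane `z = -wire_height/2` (wire top surface at `z = 0`).
#'
#' @param coil A [coil_spec()].
#' @return A data frame with columns `radius` and `z` (m), one row per turn,
#'   ordered outermost first.
#' @export
derive_loop_set <- function(coil) {
  stopifnot(inherits(coil, "coil_spec"))
  pitch <- coil$wire_width + coil$spacing
  radii <- coil$outer_radius - coil$wire_width / 2 -
    (seq_len(coil$n_turns) - 1L) * pitch
  if (any(radii <= 0))
    stop("innermost filament radius <= 0; invalid coil layout", call. = FALSE)
  data.frame(radius = radii, z = -coil$wire_height / 2)
}
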