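# structured-config file I/O.
#
# One schema, two serializations (JSON and YAML, chosen by file extension).
# Lengths are given in micrometres in files, currents in mA, flow rates in
# uL/min, diameters in nm; everything is converted to SI on load.  Unknown
# sections or keys are rejected by name.  Any key left out falls back to the
# reference configuration of the named coil (default "R2000").

.config_schema <- list(
  coil = c("name", "outer_radius_um", "n_turns", "wire_width_um",
           "wire_height_um", "spacing_um", "current_mA", "conductivity_S_m"),
  channel = c("width_um", "height_um", "length_um", "coil_separation_um",
              "lateral_offset_um"),
  fluid = c("density_kg_m3", "viscosity_Pa_s", "flow_rate_uL_min",
            "rel_permeability", "rel_permittivity"),
  particle = c("diameter_nm", "rel_permeability", "rel_permittivity",
               "mass_density_kg_m3"),
  electrodes = c("height_um", "length_um", "conductivity_S_m", "voltage_V"),
  stack = c("wall_thickness_um", "eps_wall"),
  simulation = c("horizon_s", "n_particles", "seed", "inject_time_s",
                 "series_terms", "step_length_um", "dt_max_s", "dt_min_s",
                 "rel_tol", "quadrature", "n_sub", "mnp_concentration_m3",
                 "packing_fraction"))

.read_config_file <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop(sprintf("unsupported config extension '.%s' (use .json, .yaml or .yml)",
                 ext), call. = FALSE))
  if (!is.list(raw))
    stop("config file must contain a mapping of sections", call. = FALSE)
  raw
}

.validate_config_keys <- function(raw) {
  bad_sections <- setdiff(names(raw), names(.config_schema))
  if (length(bad_sections))
    stop(sprintf("unknown config section(s): %s",
                 paste(sQuote(bad_sections), collapse = ", ")), call. = FALSE)
  for (sec in names(raw)) {
    if (!is.list(raw[[sec]]))
      stop(sprintf("config section '%s' must be a mapping", sec), call. = FALSE)
    bad <- setdiff(names(raw[[sec]]), .config_schema[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in config section '%s': %s", sec,
                   paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(raw)
}

.get_or <- function(section, key, default) {
  if (!is.null(section[[key]])) section[[key]] else default
}

#' Load a device configuration from a JSON or YAML file
#'
#' Reads the documented config schema (see
#' `system.file("extdata", "config-schema.json", package = "magsense")`),
#' rejects unknown keys by name, converts all quantities to SI, and fills any
#' omitted key from [default_device_config()] of the named coil.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` config file.
#' @return A validated [device_config()].
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  raw <- .validate_config_keys(.read_config_file(path))
  coil_name <- .get_or(raw$coil, "name", "R2000")
  if (!coil_name %in% names(.coil_catalog))
    stop(sprintf("unknown coil name '%s' (expected one of %s)", coil_name,
                 paste(names(.coil_catalog), collapse = ", ")), call. = FALSE)
  base <- default_device_config(coil_name)
  co <- raw$coil; ch <- raw$channel; fl <- raw$fluid; pa <- raw$particle
  el <- raw$electrodes; st <- raw$stack; si <- raw$simulation

  coil <- coil_spec(
    outer_radius = .get_or(co, "outer_radius_um", base$coil$outer_radius * 1e6) * 1e-6,
    n_turns      = .get_or(co, "n_turns", base$coil$n_turns),
    wire_width   = .get_or(co, "wire_width_um", base$coil$wire_width * 1e6) * 1e-6,
    wire_height  = .get_or(co, "wire_height_um", base$coil$wire_height * 1e6) * 1e-6,
    spacing      = .get_or(co, "spacing_um", base$coil$spacing * 1e6) * 1e-6,
    current      = .get_or(co, "current_mA", base$coil$current * 1e3) * 1e-3,
    conductivity = .get_or(co, "conductivity_S_m", base$coil$conductivity),
    name = coil_name)
  channel <- channel_spec(
    width  = .get_or(ch, "width_um", base$channel$width * 1e6) * 1e-6,
    height = .get_or(ch, "height_um", base$channel$height * 1e6) * 1e-6,
    length = .get_or(ch, "length_um", base$channel$length * 1e6) * 1e-6,
    coil_separation = .get_or(ch, "coil_separation_um",
                              base$channel$coil_separation * 1e6) * 1e-6,
    lateral_offset = .get_or(ch, "lateral_offset_um",
                             base$channel$lateral_offset * 1e6) * 1e-6)
  fluid <- fluid_spec(
    density   = .get_or(fl, "density_kg_m3", base$fluid$density),
    viscosity = .get_or(fl, "viscosity_Pa_s", base$fluid$viscosity),
    flow_rate = .get_or(fl, "flow_rate_uL_min",
                        base$fluid$flow_rate * 6e10) / 6e10,
    rel_permeability = .get_or(fl, "rel_permeability", base$fluid$rel_permeability),
    rel_permittivity = .get_or(fl, "rel_permittivity", base$fluid$rel_permittivity))
  particle <- particle_spec(
    diameter = .get_or(pa, "diameter_nm", base$particle$diameter * 1e9) * 1e-9,
    rel_permeability = .get_or(pa, "rel_permeability", base$particle$rel_permeability),
    rel_permittivity = .get_or(pa, "rel_permittivity", base$particle$rel_permittivity),
    mass_density = .get_or(pa, "mass_density_kg_m3", base$particle$mass_density))
  stack <- dielectric_stack(
    channel_thickness = channel$width,
    wall_thickness = .get_or(st, "wall_thickness_um",
                             base$stack$wall_thickness * 1e6) * 1e-6,
    eps_channel = fluid$rel_permittivity,
    eps_wall = .get_or(st, "eps_wall", base$stack$eps_wall))
  electrodes <- electrode_spec(
    height = .get_or(el, "height_um", base$electrodes$height * 1e6) * 1e-6,
    length = .get_or(el, "length_um", base$electrodes$length * 1e6) * 1e-6,
    gap = stack$channel_thickness + 2 * stack$wall_thickness,
    conductivity = .get_or(el, "conductivity_S_m", base$electrodes$conductivity),
    voltage = .get_or(el, "voltage_V", base$electrodes$voltage))
  sim <- sim_control(
    horizon = .get_or(si, "horizon_s", base$sim$horizon),
    n_particles = .get_or(si, "n_particles", base$sim$n_particles),
    seed = .get_or(si, "seed", base$sim$seed),
    inject_time = .get_or(si, "inject_time_s", base$sim$inject_time),
    series_terms = .get_or(si, "series_terms", base$sim$series_terms),
    step_length = .get_or(si, "step_length_um", base$sim$step_length * 1e6) * 1e-6,
    dt_max = .get_or(si, "dt_max_s", base$sim$dt_max),
    dt_min = .get_or(si, "dt_min_s", base$sim$dt_min),
    rel_tol = .get_or(si, "rel_tol", base$sim$rel_tol),
    quadrature = .get_or(si, "quadrature", base$sim$quadrature),
    n_sub = .get_or(si, "n_sub", base$sim$n_sub),
    mnp_concentration = .get_or(si, "mnp_concentration_m3",
                                base$sim$mnp_concentration),
    packing_fraction = .get_or(si, "packing_fraction",
                               base$sim$packing_fraction))
  device_config(coil = coil, channel = channel, fluid = fluid,
                particle = particle, electrodes = electrodes, stack = stack,
                sim = sim)
}

#' Write a device configuration to a JSON or YAML file
#'
#' Serializes a [device_config()] in the documented file schema (lengths in
#' micrometres, currents in mA, flow in uL/min).  `load_config()` of the
#' written file reconstructs an equal configuration.
#'
#' @param config A [device_config()].
#' @param path Output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "device_config"))
  out <- list(
    coil = list(
      name = if (is.na(config$coil$name)) NULL else config$coil$name,
      outer_radius_um = config$coil$outer_radius * 1e6,
      n_turns = config$coil$n_turns,
      wire_width_um = config$coil$wire_width * 1e6,
      wire_height_um = config$coil$wire_height * 1e6,
      spacing_um = config$coil$spacing * 1e6,
      current_mA = config$coil$current * 1e3,
      conductivity_S_m = config$coil$conductivity),
    channel = list(
      width_um = config$channel$width * 1e6,
      height_um = config$channel$height * 1e6,
      length_um = config$channel$length * 1e6,
      coil_separation_um = config$channel$coil_separation * 1e6,
      lateral_offset_um = config$channel$lateral_offset * 1e6),
    fluid = list(
      density_kg_m3 = config$fluid$density,
      viscosity_Pa_s = config$fluid$viscosity,
      flow_rate_uL_min = config$fluid$flow_rate * 6e10,
      rel_permeability = config$fluid$rel_permeability,
      rel_permittivity = config$fluid$rel_permittivity),
    particle = list(
      diameter_nm = config$particle$diameter * 1e9,
      rel_permeability = config$particle$rel_permeability,
      rel_permittivity = config$particle$rel_permittivity,
      mass_density_kg_m3 = config$particle$mass_density),
    electrodes = list(
      height_um = config$electrodes$height * 1e6,
      length_um = config$electrodes$length * 1e6,
      conductivity_S_m = config$electrodes$conductivity,
      voltage_V = config$electrodes$voltage),
    stack = list(
      wall_thickness_um = config$stack$wall_thickness * 1e6,
      eps_wall = config$stack$eps_wall),
    simulation = list(
      horizon_s = config$sim$horizon,
      n_particles = config$sim$n_particles,
      seed = config$sim$seed,
      inject_time_s = config$sim$inject_time,
      series_terms = config$sim$series_terms,
      step_length_um = config$sim$step_length * 1e6,
      dt_max_s = config$sim$dt_max,
      dt_min_s = config$sim$dt_min,
      rel_tol = config$sim$rel_tol,
      quadrature = config$sim$quadrature,
      n_sub = config$sim$n_sub,
      mnp_concentration_m3 = config$sim$mnp_concentration,
      packing_fraction = config$sim$packing_fraction))
  out$coil <- out$coil[!vapply(out$coil, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    yaml = ,
    yml = yaml::write_yaml(out, path, precision = 15L),
    stop(sprintf("unsupported config extension '.%s' (use .json, .yaml or .yml)",
                 ext), call. = FALSE))
  invisible(path)
}
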