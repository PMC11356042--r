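# Experiment drivers: the design-space sweeps behind the coil comparison,
# the trapping optimization and the capacitive sensitivity analysis, plus a
# single reproducibility report that recomputes the headline numbers.

.pkg_version <- function()
  as.character(utils::packageVersion("magsense"))

# CSV with provenance header lines (config hash, seeds, version)
.write_stamped_csv <- function(df, path, config_hash, seeds) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# magsense %s", .pkg_version()),
               sprintf("# config_hash: %s", config_hash),
               sprintf("# seeds: %s", paste(seeds, collapse = " "))), con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

.experiment_record <- function(name, results, files, config_hash, seeds,
                               elapsed) {
  structure(list(name = name, results = results, files = files,
                 config_hash = config_hash, seeds = seeds,
                 version = .pkg_version(), elapsed = elapsed),
            class = "experiment_record")
}

#' @export
print.experiment_record <- function(x, ...) {
  cat(sprintf("<experiment_record> %s: %d result table(s), config %s, %.1f s\n",
              x$name, length(x$results), x$config_hash, x$elapsed))
  invisible(x)
}

# rebuild a device config with a different channel width (stack and
# electrode gap follow the cross-component invariants)
.with_channel_width <- function(config, width) {
  channel <- channel_spec(width = width, height = config$channel$height,
                          length = config$channel$length,
                          coil_separation = config$channel$coil_separation,
                          lateral_offset = config$channel$lateral_offset)
  stack <- dielectric_stack(channel_thickness = width,
                            wall_thickness = config$stack$wall_thickness,
                            eps_channel = config$stack$eps_channel,
                            eps_wall = config$stack$eps_wall)
  electrodes <- electrode_spec(height = config$electrodes$height,
                               length = config$electrodes$length,
                               gap = width + 2 * stack$wall_thickness,
                               conductivity = config$electrodes$conductivity,
                               voltage = config$electrodes$voltage)
  device_config(config$coil, channel, config$fluid, config$particle,
                electrodes, stack, config$sim)
}

.with_separation <- function(config, k) {
  channel <- channel_spec(width = config$channel$width,
                          height = config$channel$height,
                          length = config$channel$length,
                          coil_separation = k,
                          lateral_offset = config$channel$lateral_offset)
  device_config(config$coil, channel, config$fluid, config$particle,
                config$electrodes, config$stack, config$sim)
}

.with_diameter <- function(config, d) {
  particle <- particle_spec(diameter = d,
                            rel_permeability = config$particle$rel_permeability,
                            rel_permittivity = config$particle$rel_permittivity,
                            mass_density = config$particle$mass_density)
  device_config(config$coil, config$channel, config$fluid, particle,
                config$electrodes, config$stack, config$sim)
}

#' Coil field study: profiles, ripple and power merit factors
#'
#' For each reference coil, samples the vertical decay of `Bz` at the coil
#' center, mid-annulus and outer edge, the radial profile across the turns
#' at a set of heights (with wire cross-section quadrature, for the ripple
#' analysis), the ripple metric versus height, and the power merit factor
#' over the drive-current range.
#'
#' @param out_dir Output directory for CSV tables, or `NULL` to skip
#'   writing.
#' @param coils Coil names to include.
#' @param currents Drive currents for the merit-factor table (A).
#' @param quick Logical; coarser sampling for smoke tests.
#' @return An `experiment_record` whose `results` list holds the
#'   `z_profiles`, `ripple` and `merit` tables.
#' @export
run_field_study <- function(out_dir = NULL,
                            coils = c("R500", "R1000", "R1500", "R2000"),
                            currents = seq(0.1, 0.7, by = 0.1),
                            quick = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  nz <- if (quick) 20L else 96L
  nx <- if (quick) 301L else 801L
  z_ripple <- if (quick) c(5e-6, 30e-6) else seq(5e-6, 50e-6, by = 5e-6)
  zprof <- list(); ripple <- list(); merit <- list()
  for (nm in coils) {
    cfg <- default_device_config(nm)
    coil <- cfg$coil
    loops <- derive_loop_set(coil)
    r_in <- min(loops$radius); r_out <- max(loops$radius)
    paths <- c(R0 = 0, Rint = (r_in + r_out) / 2, Rext = r_out)
    for (p in names(paths)) {
      pr <- bz_profile(coil, axis = "z", range = c(5e-6, 100e-6),
                       fixed = c(x = unname(paths[[p]]), y = 0), n = nz)
      zprof[[length(zprof) + 1L]] <-
        data.frame(coil = nm, path = p, z = pr$coord, Bz = pr$Bz, Bx = pr$Bx)
    }
    pitch <- coil$wire_width + coil$spacing
    span <- c(r_in + 2 * pitch, r_out - 2 * pitch)
    for (zv in z_ripple) {
      pr <- bz_profile(coil, axis = "x", range = span,
                       fixed = c(y = 0, z = zv), n = nx, quadrature = TRUE)
      ripple[[length(ripple) + 1L]] <-
        data.frame(coil = nm, z = zv, ripple = ripple_metric(pr, pitch))
    }
    for (cur in currents) {
      mp <- power_merit(coil, current = cur,
                        z_plane = cfg$channel$coil_separation)
      merit[[length(merit) + 1L]] <-
        data.frame(coil = nm, current = cur, Bmax = mp$Bmax,
                   resistance = mp$resistance, power = mp$power, Mp = mp$Mp)
    }
  }
  results <- list(z_profiles = do.call(rbind, zprof),
                  ripple = do.call(rbind, ripple),
                  merit = do.call(rbind, merit))
  hash <- .config_hash(list(coils, currents, quick))
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- vapply(names(results), function(nm)
      .write_stamped_csv(results[[nm]],
                         file.path(out_dir, paste0("field_", nm, ".csv")),
                         hash, integer(0)), character(1))
  }
  .experiment_record("field_study", results, files, hash, integer(0),
                     proc.time()[["elapsed"]] - t0)
}

#' Trapping-efficiency sweeps
#'
#' Runs seeded MNP ensembles over one design axis and tabulates the
#' trapping efficiency at 60 s (mean and standard deviation across seeds)
#' and the time to the steady-state trapping regime.
#'
#' Sweep grids: `"coil"` over the four reference coils; `"width"` over
#' channel widths 50, 100, 200, 500, 1000 um (R2000 coil); `"separation"`
#' over coil-channel separations 5, 10, 20, 30, 50, 100 um; `"diameter"`
#' over MNP diameters 10-60 nm.
#'
#' @param sweep One of `"coil"`, `"width"`, `"separation"`, `"diameter"`.
#' @param config Base configuration; defaults to the optimized R2000 point.
#' @param n_particles Particles per run.
#' @param seeds Integer vector of replicate seeds.
#' @param out_dir Output directory for the CSV table, or `NULL`.
#' @param points Optional subset of sweep values (SI units) replacing the
#'   default grid.
#' @return An `experiment_record` whose `results$sweep` table has one row
#'   per design point.
#' @export
run_trapping_study <- function(sweep = c("coil", "width", "separation",
                                         "diameter"),
                               config = default_device_config("R2000"),
                               n_particles = 500L, seeds = 1:3,
                               out_dir = NULL, points = NULL) {
  sweep <- match.arg(sweep)
  t0 <- proc.time()[["elapsed"]]
  grid <- switch(sweep,
    coil = c("R500", "R1000", "R1500", "R2000"),
    width = c(50, 100, 200, 500, 1000) * 1e-6,
    separation = c(5, 10, 20, 30, 50, 100) * 1e-6,
    diameter = c(10, 20, 30, 40, 50, 60) * 1e-9)
  if (!is.null(points)) grid <- points
  rows <- list()
  for (g in grid) {
    cfg <- switch(sweep,
      coil = default_device_config(g,
        n_particles = config$sim$n_particles, horizon = config$sim$horizon),
      width = .with_channel_width(config, g),
      separation = .with_separation(config, g),
      diameter = .with_diameter(config, g))
    runs <- lapply(seeds, function(s) simulate_ensemble(cfg, n_particles, s))
    eff <- trapping_efficiency(runs, t = min(60, cfg$sim$horizon))
    tss <- vapply(runs, function(r)
      as.numeric(time_to_steady_state(r)), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      sweep = sweep, value = if (is.character(g)) g else format(g),
      value_si = if (is.character(g)) NA_real_ else g,
      efficiency = as.numeric(eff), efficiency_sd = attr(eff, "sd"),
      t_steady = max(tss, na.rm = TRUE),
      config_hash = .config_hash(cfg))
  }
  results <- list(sweep = do.call(rbind, rows))
  hash <- .config_hash(list(sweep, n_particles, seeds))
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- .write_stamped_csv(results$sweep,
      file.path(out_dir, paste0("trapping_", sweep, ".csv")), hash, seeds)
  }
  .experiment_record(paste0("trapping_", sweep), results, files, hash,
                     seeds, proc.time()[["elapsed"]] - t0)
}

#' Capacitive readout study
#'
#' Tabulates the baseline capacitance versus medium permittivity, the
#' sensitivity surface over occupancy and MNP permittivity, electrode
#' height / channel width / aspect-ratio sweeps, and the dynamic
#' trap-release capacitance trace.
#'
#' @param config Base configuration; defaults to the optimized R500 point
#'   (the detection-unit coil).
#' @param out_dir Output directory for CSV tables, or `NULL`.
#' @param trace_particles Ensemble size of the dynamic-trace demo.
#' @param seed Seed of the dynamic-trace demo.
#' @return An `experiment_record` with tables `eps_curve`, `sensitivity`,
#'   `height_sweep`, `width_sweep`, `aspect_sweep`, `trace`.
#' @export
run_capacitance_study <- function(config = default_device_config("R500"),
                                  out_dir = NULL, trace_particles = 120L,
                                  seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  el <- config$electrodes; st <- config$stack
  eps_curve <- data.frame(eps_r = seq(1, 80, by = 1))
  eps_curve$C <- vapply(eps_curve$eps_r, function(e)
    stack_capacitance(el, st, eps_channel = e), numeric(1))
  surf <- expand.grid(phi = seq(0.1, 0.85, by = 0.05),
                      eps_p = c(10, 20, 30, 40))
  surf$sensitivity <- mapply(function(f, e)
    sensitivity(el, st, occupancy_state(f, e)), surf$phi, surf$eps_p)
  hs <- data.frame(height = seq(20e-6, 500e-6, by = 20e-6))
  hs$C <- vapply(hs$height, function(h)
    stack_capacitance(electrode_spec(height = h, length = el$length,
                                     gap = el$gap), st), numeric(1))
  ws <- data.frame(width = c(50, 100, 200, 500, 1000) * 1e-6)
  ws$C <- vapply(ws$width, function(w) {
    stw <- dielectric_stack(channel_thickness = w,
                            wall_thickness = st$wall_thickness,
                            eps_channel = st$eps_channel,
                            eps_wall = st$eps_wall)
    elw <- electrode_spec(height = el$height, length = el$length,
                          gap = w + 2 * stw$wall_thickness)
    stack_capacitance(elw, stw)
  }, numeric(1))
  as_grid <- data.frame(aspect = c(0.25, 0.5, 1, 2, 4))
  as_grid$C <- vapply(as_grid$aspect, function(a) {
    # width/height ratio varied at fixed channel width: H = W / a
    h <- config$channel$width / a
    stack_capacitance(electrode_spec(height = h, length = el$length,
                                     gap = el$gap), st)
  }, numeric(1))
  horizon <- config$sim$horizon
  schedule <- data.frame(start = 0, end = horizon / 2)
  trace <- dynamic_trace(config, schedule, n_particles = trace_particles,
                         seed = seed)
  results <- list(eps_curve = eps_curve, sensitivity = surf,
                  height_sweep = hs, width_sweep = ws,
                  aspect_sweep = as_grid, trace = trace)
  hash <- .config_hash(config)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- vapply(names(results), function(nm)
      .write_stamped_csv(results[[nm]],
                         file.path(out_dir, paste0("cap_", nm, ".csv")),
                         hash, seed), character(1))
  }
  .experiment_record("capacitance_study", results, files, hash, seed,
                     proc.time()[["elapsed"]] - t0)
}

#' Recompute the headline performance numbers
#'
#' Runs the whole pipeline at the optimized operating point and reports:
#' the baseline detection-zone capacitance (fF), the occupancy sensitivity
#' at occupancy 0.85 and 0.50 with MNP permittivity 10 (%), the 60 s
#' trapping efficiency of the four reference coils (%, mean over replicate
#' seeds), and the maximum across coils of the time to the steady-state
#' trapping regime (s).
#'
#' @param out_dir Directory for the JSON report, or `NULL` to skip writing.
#' @param seed Base seed; replicate seeds are derived from it.
#' @param quick Logical; reduced ensembles (80 particles, 1 seed) for smoke
#'   testing instead of the full 500 x 3.
#' @param n_particles,n_seeds Optional explicit ensemble controls.
#' @return A list with `values` (named numeric), `n` (problem sizes),
#'   `seed`, `quick`, `elapsed`.
#' @export
reproduce_report <- function(out_dir = NULL, seed = 1L, quick = TRUE,
                             n_particles = NULL, n_seeds = NULL) {
  seed <- .check_count(seed, "seed")
  t0 <- proc.time()[["elapsed"]]
  if (is.null(n_particles)) n_particles <- if (quick) 80L else 500L
  if (is.null(n_seeds)) n_seeds <- if (quick) 1L else 3L
  seeds <- (seed %% 1000000L) * 1000L + seq_len(n_seeds)

  cfg0 <- default_device_config("R2000")
  el <- cfg0$electrodes; st <- cfg0$stack
  values <- c(
    baseline_capacitance_fF = stack_capacitance(el, st) * 1e15,
    sensitivity_phi085_pct = sensitivity(el, st, occupancy_state(0.85, 10)),
    sensitivity_phi050_pct = sensitivity(el, st, occupancy_state(0.50, 10)))
  n_used <- c(baseline_capacitance_fF = 1, sensitivity_phi085_pct = 1,
              sensitivity_phi050_pct = 1)

  t_steady <- numeric(0)
  for (nm in c("R2000", "R1500", "R1000", "R500")) {
    cfg <- default_device_config(nm)
    runs <- lapply(seeds, function(s) simulate_ensemble(cfg, n_particles, s))
    key <- paste0("trap_eff_", nm, "_pct")
    values[[key]] <- as.numeric(trapping_efficiency(runs, t = 60))
    n_used[[key]] <- n_particles * n_seeds
    t_steady <- c(t_steady, vapply(runs, function(r)
      as.numeric(time_to_steady_state(r)), numeric(1)))
  }
  values[["steady_state_max_s"]] <- max(t_steady, na.rm = TRUE)
  n_used[["steady_state_max_s"]] <- 4 * n_seeds
  report <- list(values = as.list(values), n = as.list(n_used), seed = seed,
                 quick = quick, n_particles = n_particles, n_seeds = n_seeds,
                 version = .pkg_version(),
                 elapsed = proc.time()[["elapsed"]] - t0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
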