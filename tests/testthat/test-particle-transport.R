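test_that("magnetophoretic force, drag and slip follow the stated closed forms", {
  p <- particle_spec(50e-9)
  fl <- fluid_spec()
  # frozen arithmetic: 1/4 pi mu0 D^3 (4999/5002) * 1e16
  f <- magnetophoretic_force(p, fl, c(0, 0, 1e16))
  expect_equal(f[3], 1.233e-12, tolerance = 1e-3)
  expect_equal(f[1:2], c(0, 0))
  # contrast factor vanishes at matched permeability
  expect_equal(magnetophoretic_force(particle_spec(50e-9, rel_permeability = 1),
                                     fl, c(0, 0, 1e16)), c(0, 0, 0))
  # D^3 scaling
  f2 <- magnetophoretic_force(particle_spec(100e-9), fl, c(0, 0, 1e16))
  expect_equal(f2[3] / f[3], 8, tolerance = 1e-12)
  # Stokes drag: 6 pi eta r |u - vp|
  fd <- drag_force(p, fl, c(1e-3, 0, 0), c(0, 0, 0))
  expect_equal(fd[1], 4.712e-13, tolerance = 1e-3)
  expect_equal(drag_force(p, fl, c(1e-3, 2e-3, 0), c(1e-3, 2e-3, 0)),
               c(0, 0, 0))
  # linearity in the velocity difference
  expect_equal(drag_force(p, fl, c(2e-3, 0, 0), c(0, 0, 0)), 2 * fd)
  # overdamped slip: vp = u + Fmap/(6 pi eta r); ~2.62 mm/s for the example
  v <- slip_velocity(p, fl, c(0, 0, 1e16), c(1e-3, 0, 0))
  expect_equal(v[3], 2.617e-3, tolerance = 1e-3)
  expect_equal(v[1], 1e-3)
  expect_equal(slip_velocity(p, fl, c(0, 0, 0), c(5e-4, 0, 0)),
               c(5e-4, 0, 0))
  # slip scales as D^2 at fixed gradient
  v2 <- slip_velocity(particle_spec(100e-9), fl, c(0, 0, 1e16), c(0, 0, 0))
  expect_equal(v2[3] / v[3], 4, tolerance = 1e-12)
})

test_that("without coil current every particle escapes", {
  cfg <- lowflow_config(horizon = 40)
  off <- suppressWarnings(coil_spec(cfg$coil$outer_radius, cfg$coil$n_turns,
                                    current = 1e-12))
  cfg_off <- device_config(off, cfg$channel, cfg$fluid, cfg$particle,
                           sim = cfg$sim)
  res <- simulate_ensemble(cfg_off, n_particles = 50, seed = 3)
  expect_equal(res$efficiency, 0)
  expect_true(all(res$particles$status == "escaped"))
  # zero-force runs settle (at 0% trapped) almost immediately
  expect_lt(time_to_steady_state(res), 40)
})

test_that("ensembles are deterministic and conserve particle counts", {
  cfg <- lowflow_config()
  a <- simulate_ensemble(cfg, n_particles = 120, seed = 5)
  b <- simulate_ensemble(cfg, n_particles = 120, seed = 5)
  expect_identical(a$particles, b$particles)
  expect_identical(a$bins, b$bins)
  with(a$bins, expect_true(all(trapped + escaped + flowing == injected)))
  expect_true(all(a$bins$injected <= 120))
  expect_equal(a$bins$injected[nrow(a$bins)], 120)
  # status vocabulary and frozen trapped particles
  expect_true(all(a$particles$status %in% c("trapped", "escaped", "flowing")))
})

test_that("replicate seeds agree to within sampling error", {
  cfg <- default_device_config("R2000")
  e1 <- simulate_ensemble(cfg, n_particles = 400, seed = 1)$efficiency
  e2 <- simulate_ensemble(cfg, n_particles = 400, seed = 2)$efficiency
  expect_lt(abs(e1 - e2), 5)
})

test_that("trapped particles sit at walls with the magnetophoretic force pushing in", {
  cfg <- lowflow_config()
  res <- simulate_ensemble(cfg, n_particles = 150, seed = 5)
  tp <- res$particles[res$particles$status == "trapped", ]
  expect_gt(nrow(tp), 0)
  r <- cfg$particle$diameter / 2
  g <- grad_H2(cfg$coil, as.matrix(tp[, c("x", "y", "z")]))
  f <- magnetophoretic_force(cfg$particle, cfg$fluid, g)
  floor_z <- cfg$channel$coil_separation + r
  at_floor <- tp$z <= floor_z + 1e-9
  at_side <- abs(tp$y) >= cfg$channel$width / 2 - r - 1e-9
  expect_true(all(at_floor | at_side))
  expect_true(all(f[at_floor, 3] <= 0))
  if (any(at_side)) expect_true(all(sign(f[at_side, 2]) == sign(tp$y[at_side])))
  # event bookkeeping: every resolved particle has an event time
  expect_true(all(is.finite(tp$t_event)))
  expect_true(all(tp$t_event >= tp$t_inject))
})

test_that("trapping efficiency increases with particle diameter and decreases beyond 30 um separation", {
  effs_d <- vapply(c(10e-9, 30e-9, 60e-9), function(d)
    simulate_ensemble(lowflow_config(diameter = d), 150, 9)$efficiency,
    numeric(1))
  expect_true(all(diff(effs_d) >= 0))
  effs_k <- vapply(c(30e-6, 50e-6, 100e-6), function(k)
    simulate_ensemble(lowflow_config(coil_separation = k), 120, 5)$efficiency,
    numeric(1))
  expect_true(all(diff(effs_k) <= 0))
})

test_that("the overdamped reduction matches the full inertial integration", {
  cfg <- lowflow_config("R500", flow_uL_min = 0.05, horizon = 30)
  start <- c(-500e-6, 5e-6, 45e-6)
  od <- particle_trajectory(cfg, start, 0.5, inertial = FALSE, n_out = 21L)
  inr <- particle_trajectory(cfg, start, 0.5, inertial = TRUE, n_out = 21L)
  dev <- max(sqrt(rowSums((od[, 2:4] - inr[, 2:4])^2)))
  expect_lt(dev, cfg$particle$diameter)
})

test_that("outcome statistics agree with analytically constructed fixtures", {
  # constant 80% resolution rate
  fx <- fixture_trap_result("constant-rate", n = 200L, efficiency = 80)
  expect_equal(as.numeric(trapping_efficiency(fx)), 80)
  with(fx$bins, expect_true(all(trapped + escaped + flowing == injected)))
  # none trapped
  expect_equal(as.numeric(trapping_efficiency(fixture_trap_result("none-trapped"))), 0)
  # step pattern: resolved fraction switches at the change point, so the
  # window rule settles on the first 1 s bin at/after it; with injection
  # over 10 s, delay 0.5 s and change point t = 8 the answer is 8 s
  fx2 <- fixture_trap_result("step", n = 1000L, efficiency = 80,
                             efficiency_early = 20, change_point = 8,
                             resolve_delay = 0.5)
  tss <- time_to_steady_state(fx2)
  expect_true(is.finite(tss))
  f_bins <- with(fx2$bins, ifelse(trapped + escaped > 0,
                                  100 * trapped / (trapped + escaped), NA))
  f_final <- tail(stats::na.omit(f_bins), 1)
  expect_true(all(abs(stats::na.omit(f_bins[fx2$bins$t >= tss]) - f_final) <= 2))
  expect_true(any(abs(f_bins[fx2$bins$t < tss]) < f_final - 2, na.rm = TRUE))
  # guard rails
  expect_error(trapping_efficiency(fx, t = -1), "injection")
  expect_error(time_to_steady_state(fixture_trap_result("constant-rate",
                                                        horizon = 10)),
               "20 s")
})
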