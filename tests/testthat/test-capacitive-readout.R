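el50 <- electrode_spec(height = 50e-6, length = 500e-6, gap = 50e-6)
el60 <- electrode_spec(height = 50e-6, length = 500e-6, gap = 60e-6)
st <- dielectric_stack()  # 50 um channel, 5 um PDMS walls, 80 / 2.7

test_that("parallel-plate and series-stack capacitances match hand arithmetic", {
  expect_equal(parallel_plate_capacitance(el50, 80) * 1e15, 354.17,
               tolerance = 1e-4)
  expect_equal(parallel_plate_capacitance(el50, 1) * 1e15, 4.427,
               tolerance = 1e-3)
  # linear in eps_r and area, inverse in gap
  expect_equal(parallel_plate_capacitance(el50, 40),
               parallel_plate_capacitance(el50, 80) / 2)
  # Eq-9 stack: eps0*A / (dch/eps_ch + 2 dw/eps_w)
  eps0 <- 8.8541878128e-12
  expect_equal(stack_capacitance(el60, st),
               eps0 * 2.5e-8 / (50e-6 / 80 + 10e-6 / 2.7), tolerance = 1e-12)
  expect_equal(stack_capacitance(el60, st) * 1e15, 51.14, tolerance = 1e-3)
  # zero wall thickness reduces exactly to the single-layer formula
  st0 <- dielectric_stack(wall_thickness = 0)
  expect_equal(stack_capacitance(el50, st0),
               parallel_plate_capacitance(el50, 80), tolerance = 1e-12)
  # equals the harmonic combination of the three plate capacitors
  c_wall <- eps0 * 2.7 * el60$area / 5e-6
  c_ch <- eps0 * 80 * el60$area / 50e-6
  expect_equal(stack_capacitance(el60, st),
               1 / (1 / c_ch + 2 / c_wall), tolerance = 1e-12)
})

test_that("occupancy capacitance is affine in occupancy and bounded by the pure phases", {
  c0 <- occupancy_capacitance(el60, st, occupancy_state(0, 10))
  c1 <- occupancy_capacitance(el60, st, occupancy_state(1, 10))
  expect_equal(c0, stack_capacitance(el60, st), tolerance = 1e-12)
  expect_equal(c1, stack_capacitance(el60, st, eps_channel = 10),
               tolerance = 1e-12)
  # affine: two-point slope predicts the midpoint
  cm <- occupancy_capacitance(el60, st, occupancy_state(0.5, 10))
  expect_equal(cm, (c0 + c1) / 2, tolerance = 1e-12)
  phis <- seq(0, 1, by = 0.1)
  cs <- vapply(phis, function(f)
    occupancy_capacitance(el60, st, occupancy_state(f, 10)), numeric(1))
  expect_true(all(cs >= min(c0, c1) - 1e-20 & cs <= max(c0, c1) + 1e-20))
  # a particle phase matching the fluid is invisible in every mixing model
  for (m in c("parallel-column", "linear-mixture", "maxwell-garnett"))
    expect_equal(occupancy_capacitance(el60, st, occupancy_state(1, 80, m)),
                 c0, tolerance = 1e-12)
  expect_error(occupancy_state(1.2, 10), "phi")
})

test_that("sensitivity is zero at empty occupancy and monotone in phi and eps_p", {
  expect_equal(sensitivity(el60, st, occupancy_state(0, 10)), 0)
  s_phi <- vapply(seq(0.1, 0.85, by = 0.15), function(f)
    sensitivity(el60, st, occupancy_state(f, 10)), numeric(1))
  expect_true(all(diff(s_phi) > 0))
  s_eps <- vapply(c(10, 20, 30, 40), function(e)
    sensitivity(el60, st, occupancy_state(0.85, e)), numeric(1))
  expect_true(all(diff(s_eps) < 0))
  # near-linearity in phi under the parallel-column model
  s50 <- sensitivity(el60, st, occupancy_state(0.50, 10))
  s85 <- sensitivity(el60, st, occupancy_state(0.85, 10))
  expect_equal(s50 / s85, 0.50 / 0.85, tolerance = 1e-9)
})

test_that("capacitance differences carry the sign of the permittivity change", {
  expect_equal(delta_capacitance(1e-13, 1e-13), 0)
  c_before <- parallel_plate_capacitance(el50, 80)
  c_after <- parallel_plate_capacitance(el50, 20.5)
  eps0 <- 8.8541878128e-12
  expect_equal(delta_capacitance(c_before, c_after),
               eps0 * 2.5e-8 / 50e-6 * (20.5 - 80), tolerance = 1e-12)
  expect_lt(delta_capacitance(c_before, c_after), 0)
})

test_that("trapped counts convert to occupancy as volume bookkeeping dictates", {
  cfg <- default_device_config("R500")
  fx <- fixture_trap_result("constant-rate", n = 100L, efficiency = 40,
                            horizon = 60)
  occ <- occupancy_from_trap(fx, cfg)
  expect_equal(occ$phi[1], 0)
  expect_true(all(diff(occ$phi) >= 0))
  # hand computation at the horizon: 40 trapped particles (x = 0, in zone),
  # each standing for conc*Q*T_inject/n physical MNPs
  w <- cfg$sim$mnp_concentration * cfg$fluid$flow_rate *
    cfg$sim$inject_time / 100
  v_p <- pi / 6 * cfg$particle$diameter^3
  v_zone <- cfg$electrodes$length * cfg$channel$width * cfg$channel$height
  phi_exp <- min(40 * w * v_p / cfg$sim$packing_fraction / v_zone, 1)
  expect_equal(occ$phi[nrow(occ)], phi_exp, tolerance = 1e-12)
  # empty run
  occ0 <- occupancy_from_trap(fixture_trap_result("none-trapped"), cfg)
  expect_true(all(occ0$phi == 0))
  expect_error(occupancy_from_trap(fx, cfg, zone = c(-1, 1)), "domain")
})

test_that("the dynamic trace dips while the coil is on and recovers after washout", {
  cfg <- lowflow_config("R500", flow_uL_min = 0.02, horizon = 40,
                        mnp_concentration = 1e21, n_particles = 100L)
  baseline <- stack_capacitance(cfg$electrodes, cfg$stack)
  # coil never on: flat at baseline
  flat <- dynamic_trace(cfg, schedule = NULL, n_particles = 50, seed = 2)
  expect_true(all(abs(flat$C - baseline) / baseline < 1e-12))
  # one on/off cycle
  tr <- dynamic_trace(cfg, schedule = data.frame(start = 0, end = 20),
                      n_particles = 100, seed = 5)
  expect_lt(min(tr$C), baseline)             # MNPs depress the capacitance
  expect_equal(tr$t[which.min(tr$C)] <= 20, TRUE)  # minimum during coil-on
  # back to within 1% of baseline after washout
  expect_lt(abs(tr$C[nrow(tr)] - baseline) / baseline, 0.01)
  expect_error(dynamic_trace(cfg, data.frame(start = 10, end = 5)),
               "schedule")
})
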