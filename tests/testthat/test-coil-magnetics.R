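test_that("single-loop field matches the closed form on axis and the line-integral oracle off axis", {
  # on-axis closed form mu0*I/(2a)
  f <- loop_field(100e-6, 0.4, c(0, 0, 0))
  expect_equal(f$Bz, 4e-7 * pi * 0.4 / (2 * 100e-6), tolerance = 1e-12)
  expect_equal(f$Bx, 0)
  expect_equal(f$By, 0)
  # zero current
  f0 <- loop_field(100e-6, 0, c(50e-6, 20e-6, 30e-6))
  expect_equal(unlist(f0[c("Bx", "By", "Bz")]), c(Bx = 0, By = 0, Bz = 0))
  # B = mu0 * H
  expect_equal(f$Bz, 4e-7 * pi * f$Hz)
  # 100 seeded random points against the 720-node line integral
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    a <- runif(1, 50e-6, 2000e-6)
    p <- c(runif(1, -3 * a, 3 * a), runif(1, -a, a), runif(1, 10e-6, 300e-6))
    f <- loop_field(a, 0.4, p)
    B <- c(f$Bx, f$By, f$Bz)
    Bo <- oracle_loop_field(a, 0.4, p, n = 720L)
    worst <- max(worst, sqrt(sum((B - Bo)^2)) / sqrt(sum(Bo^2)))
  }
  expect_lt(worst, 1e-5)
  # singular point
  expect_error(loop_field(100e-6, 0.4, c(100e-6, 0, 0)), "filament")
})

test_that("coil field is linear in current and additive over filaments", {
  c1 <- coil_spec(500e-6, 22L, current = 0.2)
  c2 <- coil_spec(500e-6, 22L, current = 0.4)
  pts <- rbind(c(0, 0, 30e-6), c(200e-6, 40e-6, 15e-6), c(-600e-6, 0, 50e-6))
  f1 <- coil_field(c1, pts)
  f2 <- coil_field(c2, pts)
  expect_equal(2 * f1$Bz, f2$Bz, tolerance = 1e-12)
  expect_equal(2 * f1$Bx, f2$Bx, tolerance = 1e-12)
  # superposition: coil field equals the sum of its loop fields
  loops <- derive_loop_set(c2)
  acc <- 0
  for (i in seq_len(nrow(loops)))
    acc <- acc + loop_field(loops$radius[i], 0.4, pts, loop_z = loops$z[i])$Bz
  expect_equal(f2$Bz, acc, tolerance = 1e-12)
})

test_that("the field is divergence-free away from the wires", {
  coil <- default_device_config("R2000")$coil
  set.seed(3)
  d <- 1e-6
  for (i in 1:6) {
    p <- c(runif(1, -2e-3, 2e-3), runif(1, -25e-6, 25e-6),
           runif(1, 35e-6, 75e-6))
    div <- 0
    for (k in 1:3) {
      dp <- c(0, 0, 0); dp[k] <- d
      div <- div +
        (magsense:::.coil_B(coil, rbind(p + dp))[, k] -
           magsense:::.coil_B(coil, rbind(p - dp))[, k]) / (2 * d)
    }
    B <- magsense:::.coil_B(coil, rbind(p))
    expect_lt(abs(div) * d / sqrt(sum(B^2)), 1e-4)
  }
})

test_that("larger coils produce stronger fields at matched points", {
  cfgs <- lapply(c("R500", "R1000", "R1500", "R2000"), default_device_config)
  pts <- rbind(c(0, 0, 30e-6), c(100e-6, 0, 30e-6), c(0, 20e-6, 50e-6))
  bz <- vapply(cfgs, function(cfg) coil_field(cfg$coil, pts)$Bz, numeric(3))
  for (r in 1:3) expect_true(all(diff(bz[r, ]) > 0))
})

test_that("flux-density profiles are symmetric, decay with height, and order by coil size", {
  r2000 <- default_device_config("R2000")$coil
  r500 <- default_device_config("R500")$coil
  pr <- bz_profile(r2000, "x", range = c(-2100e-6, 2100e-6),
                   fixed = c(y = 0, z = 30e-6), n = 211L)
  expect_equal(pr$Bz, rev(pr$Bz), tolerance = 1e-9)
  prz <- bz_profile(r2000, "z", range = c(10e-6, 100e-6),
                    fixed = c(x = 0, y = 0), n = 46L)
  expect_true(all(diff(prz$Bz) < 0))
  # pointwise dominance over the smaller coil's span
  xs <- seq(-450e-6, 450e-6, length.out = 31L)
  b_small <- coil_field(r500, cbind(xs, 0, 30e-6))$Bz
  b_large <- coil_field(r2000, cbind(xs, 0, 30e-6))$Bz
  expect_true(all(b_large >= b_small))
})

test_that("near-field ripple decays monotonically with height", {
  coil <- default_device_config("R500")$coil
  pitch <- coil$wire_width + coil$spacing
  rip <- vapply(c(5, 10, 20, 30, 40, 50) * 1e-6, function(z) {
    pr <- bz_profile(coil, "x", range = c(115e-6, 455e-6),
                     fixed = c(y = 0, z = z), n = 401L, quadrature = TRUE)
    ripple_metric(pr, pitch)
  }, numeric(1))
  expect_true(all(diff(rip) <= 0))
  expect_gt(rip[1], rip[4])  # z = 5 um vs the 30 um working height
  # a synthetic uniform profile has zero ripple
  flat <- structure(data.frame(coord = seq(0, 200e-6, length.out = 101L),
                               Bz = 1e-3, Bx = 0), spacing = 2e-6)
  expect_equal(ripple_metric(flat, 20e-6), 0)
  short <- structure(data.frame(coord = seq(0, 50e-6, length.out = 26L),
                                Bz = 1e-3, Bx = 0), spacing = 2e-6)
  expect_error(ripple_metric(short, 20e-6), "5 wire pitches")
})

test_that("coil resistance follows the filament-length formula", {
  expect_equal(coil_resistance(default_device_config("R2000")$coil),
               105.839, tolerance = 1e-4)
  one <- coil_spec(outer_radius = 1e-3 + 5e-6, n_turns = 1L)
  expect_equal(coil_resistance(one), 2 * pi * 1e-3 / (59.6e6 * 1e-10),
               tolerance = 1e-12)
  # R scales inversely with the wire cross-section (height leaves radii fixed)
  thick <- coil_spec(500e-6, 22L, wire_height = 20e-6)
  thin <- coil_spec(500e-6, 22L, wire_height = 10e-6)
  expect_equal(coil_resistance(thin) / coil_resistance(thick), 2)
})

test_that("power merit factor halves when the current doubles and favours small coils", {
  r500 <- default_device_config("R500")$coil
  r2000 <- default_device_config("R2000")$coil
  m1 <- power_merit(r500, current = 0.2)
  m2 <- power_merit(r500, current = 0.4)
  expect_equal(m2$Mp, m1$Mp / 2, tolerance = 1e-9)
  expect_equal(m2$power, m2$voltage * 0.4, tolerance = 1e-12)
  expect_gt(power_merit(r500, 0.4)$Mp, power_merit(r2000, 0.4)$Mp)
  # Bmax is attained over the coil annulus, not at the search-domain edge
  loops <- derive_loop_set(r2000)
  expect_gt(m2$Bmax_rho, 0 - 1e-9)
  mr <- power_merit(r2000, 0.4)
  expect_lt(mr$Bmax_rho, max(loops$radius) + 10e-6)
})

test_that("straight feed segments match the infinite-wire limit and break axisymmetry", {
  rho <- 100e-6
  B <- segment_field(c(-1, 0, 0), c(1, 0, 0), 0.4, c(0, rho, 0))
  expect_equal(sqrt(sum(B^2)), 4e-7 * pi * 0.4 / (2 * pi * rho),
               tolerance = 1e-6)
  # zero field on the segment's axis extension
  expect_equal(segment_field(c(0, 0, 0), c(1, 0, 0), 0.4, c(2, 0, 0)),
               matrix(0, 1, 3))
  expect_error(segment_field(c(0, 0, 0), c(1, 0, 0), 0.4, c(0.5, 0, 0)),
               "segment")
  # feed lines make |B| asymmetric across the channel width
  coil <- default_device_config("R500")$coil
  pts <- cbind(0, seq(-25e-6, 25e-6, length.out = 11L), 30e-6)
  Bc <- magsense:::.coil_B(coil, pts)
  mag0 <- sqrt(rowSums(Bc^2))
  feeds <- list(list(start = c(495e-6, -2e-3, -5e-6), end = c(495e-6, 0, -5e-6)),
                list(start = c(-495e-6, 0, -5e-6), end = c(-495e-6, -2e-3, -5e-6)))
  Bf <- Bc
  for (f in feeds) Bf <- Bf + segment_field(f$start, f$end, coil$current, pts)
  magf <- sqrt(rowSums(Bf^2))
  expect_gt(max(abs(magf - rev(magf))), max(abs(mag0 - rev(mag0))))
})

test_that("the gridded transport gradient matches direct central differences", {
  cfg <- default_device_config("R2000")
  fg <- magsense:::.transport_field(cfg)
  set.seed(4)
  n <- 12L
  p <- cbind(runif(n, -2.3e-3, 2.3e-3), runif(n, -24e-6, 24e-6),
             runif(n, 31e-6, 79e-6))
  gdir <- grad_H2(cfg$coil, p)
  rho <- sqrt(p[, 1]^2 + p[, 2]^2)
  gr <- magsense:::.interp2(fg$rho0, fg$drho, fg$nrho, fg$z0, fg$dz, fg$nz,
                            fg$dH2drho, rho, p[, 3])
  gz <- magsense:::.interp2(fg$rho0, fg$drho, fg$nrho, fg$z0, fg$dz, fg$nz,
                            fg$dH2dz, rho, p[, 3])
  gint <- cbind(gr * p[, 1] / rho, gr * p[, 2] / rho, gz)
  rel <- sqrt(rowSums((gint - gdir)^2)) / sqrt(rowSums(gdir^2))
  expect_lt(max(rel), 1e-3)
})
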