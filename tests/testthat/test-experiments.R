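test_that("the field study tabulates profiles, ripple decay and merit factors", {
  out <- file.path(tempdir(), "field_study")
  rec <- run_field_study(out_dir = out, coils = c("R500", "R2000"),
                         currents = c(0.4, 0.7), quick = TRUE)
  expect_s3_class(rec, "experiment_record")
  expect_true(all(file.exists(rec$files)))
  merit <- rec$results$merit
  mp <- function(coil, cur) merit$Mp[merit$coil == coil & merit$current == cur]
  # the small coil wins on power merit at 400 mA
  expect_gt(mp("R500", 0.4), mp("R2000", 0.4))
  # efficiency declines at high drive current (B ~ I but P ~ I^2)
  expect_lt(mp("R2000", 0.7), mp("R2000", 0.4))
  # ripple decays between 5 um and the 30 um working height
  rip <- rec$results$ripple
  for (nm in c("R500", "R2000"))
    expect_gt(rip$ripple[rip$coil == nm & rip$z == 5e-6],
              rip$ripple[rip$coil == nm & rip$z == 30e-6])
  # vertical profiles decay with height (Bz over the annulus; |B| at the
  # outer edge, where Bz changes sign as the field wraps the last turn)
  zp <- rec$results$z_profiles
  for (p in unique(zp$path)) {
    one <- zp[zp$coil == "R2000" & zp$path == p, ]
    if (p == "Rext") {
      mag <- sqrt(one$Bz^2 + one$Bx^2)
      expect_gt(mag[1], mag[nrow(one)])
    } else {
      expect_gt(one$Bz[1], one$Bz[nrow(one)])
    }
  }
  unlink(out, recursive = TRUE)
})

test_that("trapping sweeps carry seeds, hashes and per-point statistics", {
  out <- file.path(tempdir(), "trap_study")
  cfg <- lowflow_config(horizon = 40)
  rec <- run_trapping_study("separation", config = cfg, n_particles = 60L,
                            seeds = 4L, out_dir = out,
                            points = c(30e-6, 100e-6))
  tab <- rec$results$sweep
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$efficiency >= 0 & tab$efficiency <= 100))
  expect_gte(tab$efficiency[1], tab$efficiency[2])  # weaker field farther away
  expect_true(all(nzchar(tab$config_hash)))
  # stamped CSV header carries version, hash and seeds
  header <- readLines(rec$files[1], n = 3L)
  expect_match(header[1], "magsense")
  expect_match(header[2], "config_hash")
  expect_match(header[3], "seeds: 4")
  unlink(out, recursive = TRUE)
})

test_that("the capacitance study reproduces the geometric design trends", {
  rec <- run_capacitance_study(trace_particles = 40L, seed = 3L)
  res <- rec$results
  # capacitance grows with medium permittivity and electrode height
  expect_true(all(diff(res$eps_curve$C) > 0))
  expect_true(all(diff(res$height_sweep$C) > 0))
  # and falls with channel width (larger electrode gap)
  expect_true(all(diff(res$width_sweep$C) < 0))
  # sensitivity surface: increasing in phi, decreasing in eps_p
  surf <- res$sensitivity
  s10 <- surf[surf$eps_p == 10, ]
  expect_true(all(diff(s10$sensitivity[order(s10$phi)]) > 0))
  at85 <- surf[abs(surf$phi - 0.85) < 1e-9, ]
  expect_true(all(diff(at85$sensitivity[order(at85$eps_p)]) < 0))
  # dynamic trace ends near baseline after the off half-cycle
  baseline <- res$eps_curve$C[res$eps_curve$eps_r == 80]
  expect_lt(abs(res$trace$C[nrow(res$trace)] - baseline) / baseline, 0.01)
})

test_that("the quick reproducibility report recomputes every headline quantity", {
  out <- file.path(tempdir(), "report")
  rep <- reproduce_report(out_dir = out, seed = 11, quick = TRUE,
                          n_particles = 40L)
  expect_true(file.exists(file.path(out, "report.json")))
  need <- c("baseline_capacitance_fF", "sensitivity_phi085_pct",
            "sensitivity_phi050_pct", "trap_eff_R2000_pct",
            "trap_eff_R1500_pct", "trap_eff_R1000_pct", "trap_eff_R500_pct",
            "steady_state_max_s")
  expect_true(all(need %in% names(rep$values)))
  expect_true(all(vapply(rep$values, is.numeric, logical(1))))
  loaded <- jsonlite::read_json(file.path(out, "report.json"))
  expect_true(all(need %in% names(loaded$values)))
  unlink(out, recursive = TRUE)
})
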