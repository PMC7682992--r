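# Generator checks run at reduced session lengths where the property does
# not depend on the full 15-minute duration; event-locked and occupancy
# checks use the full default.

test_that("configurations are validated", {
  expect_error(synth_config(coupling_strength = 1.2), "coupling_strength")
  expect_error(synth_config(cfc_depth = -0.1), "cfc_depth")
  expect_error(synth_config(open_frac_target = 2), "open_frac_target")
  expect_error(synth_config(fs = -1), "fs")
  expect_error(synth_config(theta_snr = Inf), "finite")
  expect_error(synth_config(duration_s = 100.0001), "integer sample count")
})

test_that("generation is seed-deterministic and finite", {
  cfg <- synth_config(duration_s = 30, seed = 5)
  a <- generate_lfp_pair(cfg)
  b <- generate_lfp_pair(cfg)
  expect_identical(a$recording$hpc, b$recording$hpc)
  expect_identical(a$recording$pfc, b$recording$pfc)
  expect_true(all(is.finite(a$recording$hpc)))
  expect_true(all(is.finite(a$recording$pfc)))
  expect_identical(length(a$truth$coupling), 30L * 2000L)
  expect_true(all(is.finite(a$truth$coupling)))
  cfg2 <- synth_config(duration_s = 30, seed = 6)
  c2 <- generate_lfp_pair(cfg2)
  expect_false(identical(a$recording$hpc, c2$recording$hpc))
})

test_that("full coupling with a quarter-cycle lag yields near-saturated theta WPLI", {
  cfg <- synth_config(duration_s = 120, coupling_strength = 1,
                      phase_lag = pi / 2, cfc_depth = 0, seed = 3)
  g <- generate_lfp_pair(cfg)
  expect_gte(wpli(g$recording$hpc, g$recording$pfc, theta_band, cfg$fs), 0.8)
  expect_identical(
    lead_lag_sign(g$recording$hpc, g$recording$pfc, theta_band, cfg$fs),
    "x_leads"
  )
})

test_that("independent channels show near-zero theta WPLI", {
  cfg <- synth_config(duration_s = 120, coupling_strength = 0, seed = 4)
  g <- generate_lfp_pair(cfg)
  expect_lte(wpli(g$recording$hpc, g$recording$pfc, theta_band, cfg$fs), 0.1)
})

test_that("the hippocampal spectrum shows a theta peak over the 1/f floor", {
  cfg <- synth_config(duration_s = 120, seed = 7)
  g <- generate_lfp_pair(cfg)
  pk <- spectral_peak(g$recording$hpc, theta_band, cfg$fs)
  expect_false(is.na(pk))
  expect_equal(pk, cfg$theta_freq, tolerance = 1.5)
})

test_that("measured coupling statistics recover the ground-truth traces", {
  # time-varying coupling session: slow wander across the full range
  cfg <- synth_config(duration_s = 600, coupling_wander = 0.25,
                      approach_gain = 1, seed = 22)
  g <- generate_lfp_pair(cfg)
  sf <- session_features(g$recording, window_s = 5, step_s = 2.5)
  w <- round(5 * cfg$fs)
  i0 <- floor((sf$time - 2.5) * cfg$fs) + 1L
  cavg <- (cumsum(g$truth$coupling)[i0 + w - 1L] -
             cumsum(g$truth$coupling)[i0 - 1L]) / w
  mavg <- (cumsum(g$truth$cfc_depth)[i0 + w - 1L] -
             cumsum(g$truth$cfc_depth)[i0 - 1L]) / w
  expect_gt(stats::cor(sf$wpli_hpcPfc_theta, cavg), 0.5)
  expect_gt(stats::cor(sf$cfc_hpcAlpha_pfcHighGamma, mavg), 0.5)
})

test_that("measured CFC increases with the programmed modulation depth", {
  mis <- vapply(c(0.1, 0.5, 0.9), function(m) {
    cfg <- synth_config(duration_s = 120, coupling_strength = 1,
                        cfc_depth = m, seed = 8)
    g <- generate_lfp_pair(cfg)
    as.numeric(cfc(g$recording$hpc, alpha_low, g$recording$pfc,
                   high_gamma, cfg$fs))
  }, numeric(1))
  expect_true(all(diff(mis) > 0))
})

test_that("trajectories meet the occupancy target and provide approach events", {
  cfg <- synth_config(seed = 11)                  # full 900 s session
  beh <- generate_epm_session(cfg)
  expect_identical(nrow(beh$track), 900L * 30L)
  lab <- classify_zones(beh$track)
  m <- occupancy_metrics(lab)
  expect_lt(abs(m$open_time_s / 900 - cfg$open_frac_target), 0.05)
  expect_gte(length(beh$events), 5)
  expect_true(all(beh$events > 0 & beh$events < 900))
  # zone times partition the session
  expect_equal(m$open_time_s + m$closed_time_s + m$center_time_s, 900,
               tolerance = 1e-6)
  # determinism
  beh2 <- generate_epm_session(cfg)
  expect_identical(beh$track, beh2$track)

  zero <- generate_epm_session(synth_config(duration_s = 300,
                                            open_frac_target = 0, seed = 12))
  labz <- classify_zones(zero$track)
  expect_identical(sum(labz$zone == "open"), 0L)
})

test_that("cohorts carry genotype structure and per-session seeds", {
  base <- synth_config(duration_s = 30, seed = 50)
  coh <- generate_cohort(7, 6, base = base)
  expect_length(coh, 13)
  expect_identical(vapply(coh, function(s) s$genotype, character(1)),
                   rep(c("WT", "Het"), c(7, 6)))
  gains <- vapply(coh, function(s) s$config$approach_gain, numeric(1))
  expect_true(all(gains[1:7] > 1))
  expect_true(all(gains[8:13] == 1))
  scales <- vapply(coh, function(s) s$config$coupling_scale, numeric(1))
  expect_true(all(scales[8:13] < scales[1:6]))
  # deterministic, and distinct across sessions
  coh2 <- generate_cohort(7, 6, base = base)
  expect_identical(coh[[1]]$recording$hpc, coh2[[1]]$recording$hpc)
  expect_false(identical(coh[[1]]$recording$hpc, coh[[2]]$recording$hpc))
  one <- generate_cohort(1, 0, base = base)
  expect_length(one, 1)
  expect_identical(one[[1]]$genotype, "WT")
})

test_that("session and track round-trip through plain CSV", {
  cfg <- synth_config(duration_s = 2, seed = 9)
  g <- generate_lfp_pair(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(g$recording, f)
  back <- read_recording_csv(f)
  expect_equal(back$fs, 2000)
  expect_equal(back$hpc, g$recording$hpc, tolerance = 1e-6)

  beh <- generate_epm_session(synth_config(duration_s = 10, seed = 9))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(beh$track, f2)
  expect_equal(read_track_csv(f2)$x_cm, beh$track$x_cm, tolerance = 1e-6)

  f3 <- withr::local_tempfile(fileext = ".yaml")
  write_synth_config_yaml(cfg, f3)
  expect_equal(read_synth_config_yaml(f3), cfg)
})
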