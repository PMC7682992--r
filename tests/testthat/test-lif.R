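test_that("Poisson generation matches target rates and the (1 - cos) profile", {
  set.seed(1)
  counts <- replicate(500, length(inhomogeneous_poisson(50, 1)))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 50), 3 * se + 1e-9)

  expect_length(inhomogeneous_poisson(0, 1), 0)
  expect_error(inhomogeneous_poisson(-5, 1), "rate")
  expect_error(inhomogeneous_poisson(5000, 1, dt_ms = 0.1), "refine")

  # sinusoidal 0-100 Hz: mean ~50 Hz, phase histogram follows (1 - cos)
  spec <- input_spec()
  rate_fn <- thetacomm:::hpc_rate_fn(spec)
  set.seed(2)
  spikes <- unlist(lapply(1:2000, function(i) inhomogeneous_poisson(rate_fn, 1)))
  expect_equal(length(spikes) / 2000, 50, tolerance = 0.05 * 50)
  ph <- (spikes * spec$f) %% 1
  edges <- seq(0, 1, length.out = 21)
  h <- table(cut(ph, breaks = edges))
  # expected bin probabilities: exact integral of (1 - cos) over each bin
  cdf <- edges - sin(2 * pi * edges) / (2 * pi)
  p_exp <- diff(cdf) / max(cdf)
  gof <- suppressWarnings(stats::chisq.test(as.numeric(h), p = p_exp))
  expect_gt(gof$p.value, 0.01)
})

test_that("circuit parameter invariants are enforced", {
  expect_error(circuit_params(tau_e = -1), "positive")
  expect_error(circuit_params(dt_ms = 5), "dt_ms")
  expect_error(circuit_params(w_fsin_pyr = 0.5), "inhibitory")
})

test_that("simulator base cases: silence, refractory ceiling, inhibition monotonicity", {
  p <- circuit_params(w_hpc_pyr = 1.5, w_noise_pyr = 1.5,
                      w_hpc_fsin = 1, w_noise_fsin = 1, w_fsin_pyr = -1)
  zeros <- integer(10000)
  st <- simulate_circuit(p, zeros, zeros)
  expect_length(st$pyr, 0)
  expect_length(st$fsin, 0)

  # saturating drive: rate bounded by the refractory period (500 Hz at 2 ms)
  p_sat <- circuit_params(w_hpc_pyr = 50, w_noise_pyr = 50, w_fsin_pyr = 0)
  set.seed(3)
  inp <- thetacomm:::draw_inputs(input_spec(), 0.1)
  st_sat <- simulate_circuit(p_sat, inp$hpc, inp$noise)
  expect_lte(length(st_sat$pyr), 500)
  expect_gt(length(st_sat$pyr), 100)

  # stronger inhibition never raises the mean pyramidal rate
  rates <- vapply(c(0, 1, 3), function(wm) {
    pm <- thetacomm:::modify_params(p, w_hpc_pyr = 2.3, w_noise_pyr = 2.3,
                                    w_fsin_pyr = -wm)
    tr <- thetacomm:::run_trials(pm, input_spec(), seed = 11, iterations = 60)
    mean(tr$rate_pyr)
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("compiled and reference integrators are spike-identical at fine dt", {
  p <- circuit_params(dt_ms = 0.01, w_hpc_pyr = 2.3, w_noise_pyr = 2.3,
                      w_hpc_fsin = 1.3, w_noise_fsin = 1.3, w_fsin_pyr = -2,
                      w_hpc_isi = 0.5, w_noise_isi = 0.5, w_isi_fsin = -0.5)
  set.seed(4)
  inp <- thetacomm:::draw_inputs(input_spec(), 0.01)
  fast <- simulate_circuit(p, inp$hpc, inp$noise)
  slow <- simulate_circuit(p, inp$hpc, inp$noise, reference = TRUE)
  expect_identical(fast, slow)
  expect_gt(length(fast$pyr) + length(fast$fsin) + length(fast$isi), 0)
})

test_that("binned correlation: identity, independence, jitter decorrelation", {
  set.seed(5)
  a <- sort(runif(80, 0, 1))
  expect_equal(binned_correlation(a, a, 1), 1)

  rs <- replicate(400, {
    binned_correlation(runif(50), runif(50), 1)
  })
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs)), 3 * se + 1e-9)

  rj <- replicate(200, {
    x <- runif(60)
    y <- (x + runif(60, -0.2, 0.2)) %% 1   # jitter >> 10 ms bin
    binned_correlation(x, y, 1)
  })
  expect_lt(abs(mean(rj)), 0.05)

  z <- binned_correlation(numeric(0), a, 1)
  expect_identical(as.numeric(z), 0)
  expect_true(isTRUE(attr(z, "degenerate")))
})

test_that("calibration handles trivial and infeasible target sets", {
  z <- calibrate_operating_point(targets = c(fsin = 0, pyr_inh = 0,
                                             pyr_noinh = 0))
  expect_true(z$feasible)
  expect_identical(z$params$w_fsin_pyr, 0)
  expect_error(
    calibrate_operating_point(targets = c(fsin = 20, pyr_inh = 60,
                                          pyr_noinh = 50)),
    "infeasible"
  )
})

test_that("zero feedforward drive reproduces the uninhibited circuit and zero-ISI reduces exactly", {
  p <- circuit_params(w_hpc_pyr = 2.3, w_noise_pyr = 2.3,
                      w_hpc_fsin = 1.3, w_noise_fsin = 1.3, w_fsin_pyr = -2)
  sw <- sweep_fsin_drive(p, grid = c(0, 1), reps = 60, seed = 21)
  expect_equal(sw$rate_fsin[1], 0)
  tr0 <- thetacomm:::run_trials(thetacomm:::modify_params(p, w_fsin_pyr = 0),
                                input_spec(), seed = 21, iterations = 60)
  expect_equal(sw$rate_pyr[1], mean(tr0$rate_pyr),
               tolerance = 3 * sd(tr0$rate_pyr) / sqrt(60) / mean(tr0$rate_pyr))
  # FSIN rate grows with its drive
  expect_gt(sw$rate_fsin[2], sw$rate_fsin[1])

  base <- sweep_fsin_drive(p, grid = c(0.5, 1.5), reps = 40, seed = 22)
  red <- disinhibition_variant(p, grid = c(0.5, 1.5), w_isi = 0,
                               w_isi_fsin = 0, reps = 40, seed = 22)
  expect_equal(as.data.frame(base), as.data.frame(red))

  # active disinhibition suppresses the FSIN at matched drive
  dis <- disinhibition_variant(p, grid = c(0.5, 1.5), w_isi = 1.3,
                               w_isi_fsin = -2, reps = 40, seed = 22)
  expect_lt(dis$rate_fsin[2], base$rate_fsin[2])
  expect_gt(dis$rate_pyr[2], base$rate_pyr[2])
})

test_that("frequency sweep is reproducible under a fixed seed", {
  p <- circuit_params(w_hpc_pyr = 2.3, w_noise_pyr = 2.3,
                      w_hpc_fsin = 1.3, w_noise_fsin = 1.3, w_fsin_pyr = -2)
  f1 <- frequency_sweep(p, f_values = c(4, 8), reps = 20, seed = 31)
  f2 <- frequency_sweep(p, f_values = c(4, 8), reps = 20, seed = 31)
  expect_identical(f1, f2)
  expect_error(frequency_sweep(p, f_values = c(0, 8)), "frequencies")
})
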