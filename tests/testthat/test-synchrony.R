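fs <- 2000

test_that("WPLI saturates for lagged copies, vanishes for zero lag, small for independent noise", {
  n <- 120 * fs
  z <- nb_noise(n, 6, 10, fs, seed = 1)
  x <- Re(z)
  y <- Re(z * exp(-1i * pi / 2))          # quarter-cycle lag
  expect_gte(wpli(x, y, theta_band, fs), 0.95)
  expect_identical(wpli(x, x, theta_band, fs), 0)

  nulls <- vapply(1:3, function(i) {
    x2 <- Re(nb_noise(n, 6, 10, fs, seed = 1 + 2 * i))
    y2 <- Re(nb_noise(n, 6, 10, fs, seed = 2 + 2 * i))
    wpli(x2, y2, theta_band, fs)
  }, numeric(1))
  expect_lte(mean(nulls), 0.1)
  expect_error(wpli(x, y[-1], theta_band, fs), "equal length")
})

test_that("WPLI is scale-invariant, symmetric and bounded", {
  n <- 30 * fs
  z <- nb_noise(n, 6, 10, fs, seed = 4)
  x <- Re(z); y <- Re(z * exp(-1i * 0.6)) + 0.2 * rnorm(n)
  w0 <- wpli(x, y, theta_band, fs)
  expect_true(w0 >= 0 && w0 <= 1)
  expect_equal(wpli(5 * x, y, theta_band, fs), w0, tolerance = 1e-12)
  expect_equal(wpli(x, 0.3 * y, theta_band, fs), w0, tolerance = 1e-12)
  expect_equal(wpli(y, x, theta_band, fs), w0, tolerance = 1e-12)
})

test_that("vectorized WPLI and CFC match naive per-sample loops", {
  n <- 4 * fs
  zx <- nb_noise(n, 6, 10, fs, seed = 5)
  zy <- nb_noise(n, 6, 10, fs, seed = 6) + 0.4 * zx
  expect_equal(thetacomm:::wpli_analytic(zx, zy), wpli_loop(zx, zy),
               tolerance = 1e-10)
  phase <- Arg(zx)
  amp <- Mod(zy)
  expect_equal(as.numeric(thetacomm:::cfc_phase_amp(phase, amp)),
               cfc_loop(phase, amp), tolerance = 1e-10)
})

test_that("lead/lag sign follows the delay convention", {
  n <- 30 * fs
  z <- nb_noise(n, 6, 10, fs, seed = 7)
  x <- Re(z)
  y <- Re(z * exp(-1i * pi / 3))
  expect_identical(lead_lag_sign(x, y, theta_band, fs), "x_leads")
  expect_identical(lead_lag_sign(y, x, theta_band, fs), "y_leads")
  expect_identical(lead_lag_sign(x, x, theta_band, fs), "indeterminate")
})

test_that("amplitude covariation tracks shared, independent and anti-phase envelopes", {
  n <- 90 * fs
  set.seed(8)
  t <- seq_len(n) / fs
  env <- 1 + 0.5 * sin(2 * pi * 0.4 * t)   # slow common envelope in [0.5, 1.5]
  # constant-amplitude carriers at distinct in-band frequencies, so the
  # instantaneous amplitudes are the envelopes themselves
  c1 <- cos(2 * pi * 7.4 * t)
  c2 <- cos(2 * pi * 8.7 * t + 1)
  expect_gte(amplitude_covariation(env * c1, env * c2, theta_band, fs), 0.9)

  e1 <- 1 + 0.5 * sin(2 * pi * 0.4 * t)
  e2 <- 1 + 0.5 * sin(2 * pi * 0.53 * t + 1)
  expect_lte(abs(amplitude_covariation(e1 * c1, e2 * c2, theta_band, fs)), 0.1)

  anti <- 2 - env                          # anti-phase envelope
  expect_lte(amplitude_covariation(env * c1, anti * c2, theta_band, fs), -0.9)

  flat <- amplitude_covariation(numeric(n) , numeric(n), theta_band, fs)
  expect_identical(as.numeric(flat), 0)
  expect_true(isTRUE(attr(flat, "degenerate")))
})

test_that("CFC modulation index approaches m/2 and is monotone in depth", {
  # numerical-integral oracle for the asymptotic value
  oracle <- function(m) {
    re <- stats::integrate(function(p) (1 + m * cos(p)) * cos(p), -pi, pi)$value
    im <- stats::integrate(function(p) (1 + m * cos(p)) * sin(p), -pi, pi)$value
    tot <- stats::integrate(function(p) 1 + m * cos(p), -pi, pi)$value
    sqrt(re^2 + im^2) / tot
  }
  expect_equal(oracle(0.6), 0.3, tolerance = 1e-8)

  n <- 120 * fs
  # the statistic itself on a constructed (phase, amplitude) series with
  # uniform phase coverage: the stated closed form
  zl <- nb_noise(n, 7, 9, fs, seed = 9)
  phi <- Arg(zl)
  amp <- 1 + 0.6 * cos(phi)
  expect_lt(abs(as.numeric(thetacomm:::cfc_phase_amp(phi, amp)) - oracle(0.6)),
            0.02)

  # full signal path: the short high-band kernel (3 periods of 65 Hz)
  # attenuates the AM sidebands; the independent oracle corrects the
  # closed form by the designed kernel's own squared response
  t <- seq_len(n) / fs
  carrier <- cos(2 * pi * 82.5 * t)
  b <- design_fir(high_gamma, fs)
  H2 <- function(f) Mod(sum(b * exp(-2i * pi * f / fs * (seq_along(b) - 1))))^2
  side <- mean(vapply(seq(7, 9, by = 0.25),
                      function(f0) (H2(82.5 - f0) + H2(82.5 + f0)) / 2,
                      numeric(1))) / H2(82.5)
  mis <- vapply(c(0.2, 0.4, 0.6, 0.8), function(m) {
    as.numeric(cfc(Re(zl), alpha_low, (1 + m * cos(phi)) * carrier,
                   high_gamma, fs))
  }, numeric(1))
  expect_lt(abs(mis[3] - side * oracle(0.6)), 0.02)
  expect_true(all(diff(mis) > 0))
  expect_true(all(mis >= 0 & mis <= 1))
})

test_that("CFC degenerate and extreme cases follow the stated conventions", {
  n <- 60 * fs
  zl <- nb_noise(n, 7, 9, fs, seed = 10)
  t <- seq_len(n) / fs
  # constant high-band amplitude: uniform-phase cancellation
  expect_lt(as.numeric(cfc(Re(zl), alpha_low, cos(2 * pi * 82.5 * t),
                           high_gamma, fs)), 0.03)
  # all amplitude at one phase: unit mean vector
  phase <- rep(1.3, 1000)
  expect_equal(as.numeric(thetacomm:::cfc_phase_amp(phase, runif(1000))), 1)
  # zero amplitude flagged
  z0 <- thetacomm:::cfc_phase_amp(runif(1000, -pi, pi), numeric(1000))
  expect_identical(as.numeric(z0), 0)
  expect_true(isTRUE(attr(z0, "degenerate")))
  # rescaling the amplitude leaves the index unchanged
  ph <- runif(5000, -pi, pi); am <- rexp(5000)
  expect_equal(as.numeric(thetacomm:::cfc_phase_amp(ph, am)),
               as.numeric(thetacomm:::cfc_phase_amp(ph, 7 * am)),
               tolerance = 1e-12)
})
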