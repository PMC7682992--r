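# Shared fixture builders: every fixture is generated in code at test time.

# Band-limited Gaussian noise as analytic signal (test-local construction,
# independent of the package generator where used as an oracle input).
nb_noise <- function(n, lo, hi, fs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- thetacomm:::band_analytic(rnorm(n), band_spec("nb", lo, hi), fs)
  z / stats::sd(Re(z))
}

theta_band <- band_spec("theta", 4, 12)
alpha_low <- band_spec("Alpha", 6, 10)
high_gamma <- band_spec("HighGamma", 65, 100)

# Per-sample loop references for the synchrony statistics: deliberately
# naive implementations used as oracles against the vectorized paths.
wpli_loop <- function(zx, zy) {
  num <- 0; den <- 0
  for (i in seq_along(zx)) {
    s <- zx[i] * Conj(zy[i])
    num <- num + Im(s)
    den <- den + abs(Im(s))
  }
  if (den == 0) 0 else abs(num) / den
}

cfc_loop <- function(phase, amp) {
  acc <- 0 + 0i; tot <- 0
  for (i in seq_along(phase)) {
    acc <- acc + amp[i] * exp(1i * phase[i])
    tot <- tot + amp[i]
  }
  if (tot == 0) 0 else Mod(acc) / tot
}

# Rectangular EPM path helper: constant-position segments with given zone
# dwell times at 10 Hz.
path_track <- function(segments, fs = 10) {
  rows <- lapply(segments, function(seg) {
    n <- round(seg$dwell * fs)
    data.frame(x_cm = rep(seg$x, n), y_cm = rep(seg$y, n))
  })
  df <- do.call(rbind, rows)
  tibble::tibble(time_s = (seq_len(nrow(df)) - 1) / fs,
                 x_cm = df$x_cm, y_cm = df$y_cm)
}
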