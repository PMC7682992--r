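#' Weighted phase-lag index
#'
#' Phase synchrony between two channels in a frequency band, using only the
#' imaginary part of the per-sample cross-term `S = z_x * Conj(z_y)` of the
#' band-limited analytic signals:
#' `WPLI = |mean(Im S)| / mean(|Im S|)`, in `[0, 1]`. Because the real part
#' is discarded, instantaneous (zero-lag) mixing such as volume conduction
#' does not inflate the statistic; a consistent nonzero phase lag drives it
#' to 1. When `mean(|Im S|) == 0` (e.g. `y` identical to `x`) the statistic
#' is defined as 0: no imaginary structure means no measurable lagged
#' synchrony.
#'
#' Inputs are zero-phase filtered to the band, half a filter length is
#' trimmed from each end to discard Hilbert edge transients, and the plain
#' (non-debiased) ratio is returned; `debias = TRUE` applies the
#' squared-WPLI debiasing correction instead.
#'
#' @param x,y Equal-length numeric signals (`x` conventionally the
#'   hippocampal channel).
#' @param band A [band_spec()].
#' @param fs Sampling rate (samples/s).
#' @param debias Use the debiased squared estimator (default `FALSE`).
#' @return Scalar in `[0, 1]`.
#' @export
wpli <- function(x, y, band, fs, debias = FALSE) {
  z <- band_pair_analytic(x, y, band, fs)
  wpli_analytic(z$zx, z$zy, debias = debias)
}

band_pair_analytic <- function(x, y, band, fs) {
  if (length(x) != length(y)) stop("signals must have equal length", call. = FALSE)
  zx <- band_analytic(x, band, fs)
  zy <- band_analytic(y, band, fs)
  trim <- edge_trim_samples(band, fs)
  if (length(x) <= 2L * trim + 2L) stop("signal too short for band", call. = FALSE)
  keep <- (trim + 1L):(length(x) - trim)
  list(zx = zx[keep], zy = zy[keep])
}

# Estimator core on precomputed analytic signals (also the unit the
# per-sample loop oracle is checked against).
wpli_analytic <- function(zx, zy, debias = FALSE) {
  im <- Im(zx * Conj(zy))
  denom <- mean(abs(im))
  if (denom == 0) return(0)
  if (!debias) {
    abs(mean(im)) / denom
  } else {
    n <- length(im)
    num <- sum(im)^2 - sum(im^2)
    den <- sum(abs(im))^2 - sum(im^2)
    if (den <= 0) return(0)
    sqrt(max(num / den, 0))
  }
}

#' Lead/lag direction of band-limited synchrony
#'
#' Sign of `mean(Im S)` with `S = z_x * Conj(z_y)`. Positive means `x`
#' leads `y` (with `x` the hippocampal channel, hippocampus leading
#' prefrontal cortex).
#'
#' @inheritParams wpli
#' @param tol Magnitudes of the mean imaginary part below `tol` times the
#'   mean `|Im S|` are reported as indeterminate.
#' @return One of `"x_leads"`, `"y_leads"`, `"indeterminate"`.
#' @export
lead_lag_sign <- function(x, y, band, fs, tol = 1e-6) {
  z <- band_pair_analytic(x, y, band, fs)
  im <- Im(z$zx * Conj(z$zy))
  denom <- mean(abs(im))
  if (denom == 0 || abs(mean(im)) < tol * denom) return("indeterminate")
  if (mean(im) > 0) "x_leads" else "y_leads"
}

#' Amplitude covariation between channels
#'
#' Pearson correlation of the instantaneous band amplitudes of the two
#' channels. If either amplitude is constant the correlation is undefined
#' and 0 is returned with attribute `degenerate = TRUE`.
#'
#' @inheritParams wpli
#' @return Scalar in `[-1, 1]` (attribute `degenerate` when flagged).
#' @export
amplitude_covariation <- function(x, y, band, fs) {
  z <- band_pair_analytic(x, y, band, fs)
  ampcov_amplitudes(Mod(z$zx), Mod(z$zy))
}

ampcov_amplitudes <- function(ax, ay) {
  if (stats::sd(ax) == 0 || stats::sd(ay) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  stats::cor(ax, ay)
}

#' Phase-amplitude cross-frequency coupling
#'
#' Modulation index of a high band's instantaneous amplitude by a low
#' band's instantaneous phase. Each time point contributes the complex
#' vector `A_hi(t) * exp(1i * phi_lo(t))`; the modulus of the vector sum,
#' normalized by the sum of the amplitudes, is the coupling strength:
#' `MI = |sum(A * exp(1i phi))| / sum(A)`, in `[0, 1]`. For a sinusoidal
#' amplitude modulation of depth `m` with uniform phase coverage the
#' statistic converges to `m / 2`.
#'
#' The phase source and amplitude source may be the same or different
#' channels, covering all within- and cross-region combinations.
#'
#' @param phase_signal Signal supplying the low-band phase.
#' @param low_band [band_spec()] for the phase.
#' @param amp_signal Signal supplying the high-band amplitude.
#' @param high_band [band_spec()] for the amplitude.
#' @param fs Sampling rate (samples/s).
#' @return Scalar in `[0, 1]` (attribute `degenerate` when the high-band
#'   amplitude is identically zero).
#' @export
cfc <- function(phase_signal, low_band, amp_signal, high_band, fs) {
  if (length(phase_signal) != length(amp_signal)) {
    stop("signals must have equal length", call. = FALSE)
  }
  zl <- band_analytic(phase_signal, low_band, fs)
  zh <- band_analytic(amp_signal, high_band, fs)
  trim <- max(edge_trim_samples(low_band, fs), edge_trim_samples(high_band, fs))
  if (length(phase_signal) <= 2L * trim + 2L) {
    stop("signal too short for bands", call. = FALSE)
  }
  keep <- (trim + 1L):(length(phase_signal) - trim)
  cfc_phase_amp(Arg(zl[keep]), Mod(zh[keep]))
}

cfc_phase_amp <- function(phase, amp) {
  total <- sum(amp)
  if (total == 0) return(structure(0, degenerate = TRUE))
  Mod(sum(amp * exp(1i * phase))) / total
}
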