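#' Welch power spectral density with nonoverlapping segments
#'
#' Splits the signal into nonoverlapping segments (default 2 s), applies a
#' Hamming window to each, and averages the periodograms. The density is
#' one-sided and normalized so that summing `psd * df` over all frequencies
#' recovers the signal's mean power.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (samples/s).
#' @param segment_s Segment length in seconds (default 2).
#' @return Tibble with columns `freq` (Hz) and `psd` (power/Hz).
#' @export
welch_psd <- function(x, fs, segment_s = 2) {
  nseg <- floor(segment_s * fs)
  n <- length(x)
  if (nseg < 2 || nseg > n) {
    stop("need at least one full segment", call. = FALSE)
  }
  k <- floor(n / nseg)
  w <- hamming_window(nseg)
  norm <- fs * sum(w^2)
  nhalf <- floor(nseg / 2) + 1L
  acc <- numeric(nhalf)
  for (i in seq_len(k)) {
    seg <- x[((i - 1L) * nseg + 1L):(i * nseg)] * w
    P <- Mod(stats::fft(seg))^2 / norm
    half <- P[seq_len(nhalf)]
    # one-sided: double everything except DC (and Nyquist when nseg is even)
    half[2:(nhalf - 1L)] <- 2 * half[2:(nhalf - 1L)]
    if (nseg %% 2 == 1) half[nhalf] <- 2 * half[nhalf]
    acc <- acc + half
  }
  tibble::tibble(
    freq = (seq_len(nhalf) - 1L) * fs / nseg,
    psd = acc / k
  )
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Band power from the Welch estimate
#'
#' Integrates the one-sided Welch density over the closed band `[lo, hi]`.
#'
#' @inheritParams welch_psd
#' @param band A [band_spec()].
#' @return Nonnegative scalar power.
#' @export
#' @examples
#' fs <- 1000
#' x <- sin(2 * pi * 8 * seq(0, 10, by = 1 / fs))
#' band_power(x, band_spec("theta", 4, 12), fs)  # ~0.5
band_power <- function(x, band, fs, segment_s = 2) {
  check_band_nyquist(band, fs)
  spec <- welch_psd(x, fs, segment_s)
  df <- spec$freq[2] - spec$freq[1]
  sel <- spec$freq >= band$lo & spec$freq <= band$hi
  sum(spec$psd[sel]) * df
}

#' Detect a spectral peak within a band
#'
#' Returns the frequency of the largest local maximum of the Welch density
#' inside the band, or `NA` if the density is monotone there. Used to screen
#' hippocampal channels for a visible theta peak.
#'
#' @inheritParams band_power
#' @return Peak frequency in Hz, or `NA_real_`.
#' @export
spectral_peak <- function(x, band, fs, segment_s = 2) {
  spec <- welch_psd(x, fs, segment_s)
  sel <- which(spec$freq >= band$lo & spec$freq <= band$hi)
  if (length(sel) < 3) return(NA_real_)
  p <- spec$psd[sel]
  interior <- which(diff(sign(diff(p))) == -2) + 1L
  if (!length(interior)) return(NA_real_)
  best <- interior[which.max(p[interior])]
  spec$freq[sel[best]]
}
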