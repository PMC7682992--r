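#' Design the band-pass FIR kernel for a band
#'
#' Kernel length is three periods of the band's lower edge
#' (`round(3 * fs / lo)` samples), Hamming-windowed linear-phase design.
#' Forcing an odd length keeps the kernel symmetric (type I), so the
#' forward-backward application in [bandpass()] is exactly zero phase.
#'
#' @param band A [band_spec()].
#' @param fs Sampling rate (samples/s).
#' @return Numeric vector of FIR coefficients.
#' @export
design_fir <- function(band, fs) {
  check_band_nyquist(band, fs)
  len <- round(3 * fs / band$lo)
  if (len %% 2 == 0) len <- len + 1
  signal::fir1(len - 1, c(band$lo, band$hi) / (fs / 2), type = "pass")
}

check_band_nyquist <- function(band, fs) {
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  if (band$hi > fs / 2) {
    stop(sprintf("band %s (%g-%g Hz) exceeds Nyquist %g Hz",
                 band$name, band$lo, band$hi, fs / 2), call. = FALSE)
  }
  invisible(TRUE)
}

# FFT size: smallest power of two >= n (keeps big transforms fast).
next_pow2 <- function(n) 2^ceiling(log2(n))

# Linear convolution of x with the autocorrelation of kernel b via FFT,
# aligned so the output has zero group delay: equivalent to filtering
# forward then backward with b (zero-padded edges).
fir_filtfilt <- function(x, b) {
  n <- length(x)
  L <- length(b)
  if (n <= L) stop("signal shorter than filter kernel", call. = FALSE)
  nfft <- next_pow2(n + 2L * L)
  B <- stats::fft(c(b, rep(0, nfft - L)))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  # B * Conj(B) is the transform of the kernel autocorrelation centred at
  # lag zero, so the filtered signal is already delay-free
  y <- Re(stats::fft(X * B * Conj(B), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

#' Zero-phase band-pass filtering
#'
#' Applies the Hamming-window FIR kernel from [design_fir()] forward and
#' backward (via FFT convolution with the kernel autocorrelation), giving a
#' zero-phase band-limited signal of the same length as the input.
#'
#' @param x Numeric signal.
#' @inheritParams design_fir
#' @return Filtered signal, same length as `x`.
#' @export
#' @examples
#' fs <- 500
#' t <- seq(0, 4, by = 1 / fs)
#' x <- sin(2 * pi * 8 * t) + sin(2 * pi * 60 * t)
#' y <- bandpass(x, band_spec("theta", 4, 12), fs)
bandpass <- function(x, band, fs) {
  if (anyNA(x) || !all(is.finite(x))) stop("signal must be finite", call. = FALSE)
  fir_filtfilt(x, design_fir(band, fs))
}

# Samples corrupted by edge transients at each end: half a kernel length.
edge_trim_samples <- function(band, fs) {
  ceiling(round(3 * fs / band$lo) / 2)
}

#' Analytic signal via the Hilbert transform
#'
#' Returns the complex analytic signal whose modulus is the instantaneous
#' amplitude and whose argument the instantaneous phase of a band-limited
#' input. `amplitude_phase()` is a convenience wrapper returning both as a
#' tibble.
#'
#' @param x Real band-limited signal.
#' @return `analytic()`: complex vector, same length as `x`.
#' @export
analytic <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty signal", call. = FALSE)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' @rdname analytic
#' @return `amplitude_phase()`: tibble with columns `amplitude`, `phase`.
#' @export
amplitude_phase <- function(x) {
  z <- analytic(x)
  tibble::tibble(amplitude = Mod(z), phase = Arg(z))
}

# One-pass band-limited analytic signal: multiply the padded spectrum by the
# zero-phase filter response |B(f)|^2 and the analytic-signal step, then
# inverse transform. Used by the bulk feature extractor where filtering and
# Hilbert transform are always composed.
band_analytic <- function(x, band, fs, x_fft = NULL, nfft = NULL,
                          max_kernel = Inf) {
  n <- length(x)
  len <- round(3 * fs / band$lo)
  if (len %% 2 == 0) len <- len + 1
  if (len > min(max_kernel, floor(n / 3))) {
    # cap the kernel for very slow bands on short signals
    len <- min(max_kernel, floor(n / 3))
    if (len %% 2 == 0) len <- len - 1L
    len <- max(len, 5L)
  }
  check_band_nyquist(band, fs)
  b <- signal::fir1(len - 1, c(band$lo, band$hi) / (fs / 2), type = "pass")
  L <- length(b)
  if (is.null(nfft)) nfft <- next_pow2(n + 2L * L)
  if (is.null(x_fft)) x_fft <- stats::fft(c(x, rep(0, nfft - n)))
  B <- stats::fft(c(b, rep(0, nfft - L)))
  h <- numeric(nfft)
  h[1] <- 1; h[nfft / 2 + 1] <- 1; h[2:(nfft / 2)] <- 2
  z <- stats::fft(x_fft * (B * Conj(B)) * h, inverse = TRUE) / nfft
  z[seq_len(n)]
}
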