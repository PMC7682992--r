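#' Event-locked analysis window grid
#'
#' Dynamic (event-locked) measures use a 2.5 s window advanced in 1.5 s
#' steps from 7.5 s before to 7.5 s after the event, i.e. 11 grid points
#' per event at offsets -7.5, -6, ..., +7.5 s.
#'
#' @param window_s Window length in seconds (default 2.5).
#' @param step_s Step between window centres in seconds (default 1.5).
#' @param span_s Half-span around the event in seconds (default 7.5).
#' @return A `dynamic_window_spec` list; `$offsets` holds the grid.
#' @export
dynamic_window_spec <- function(window_s = 2.5, step_s = 1.5, span_s = 7.5) {
  stopifnot(window_s > 0, step_s > 0, span_s > 0)
  k <- round(span_s / step_s)
  if (abs(k * step_s - span_s) > 1e-9) {
    stop("span_s must be an integer multiple of step_s", call. = FALSE)
  }
  structure(
    list(
      window_s = window_s, step_s = step_s, span_s = span_s,
      offsets = seq(-span_s, span_s, by = step_s)
    ),
    class = "dynamic_window_spec"
  )
}

# Window index ranges for centres `tc` (seconds). Returns NULL rows marked
# invalid when a window (plus the filter edge trim) leaves the session.
window_indices <- function(tc, fs, window_s, n, trim) {
  wlen <- round(window_s * fs)
  i0 <- floor((tc - window_s / 2) * fs) + 1L
  i1 <- i0 + wlen - 1L
  ok <- i0 >= trim + 1L & i1 <= n - trim
  list(i0 = i0, i1 = i1, ok = ok, wlen = wlen)
}

wsum <- function(cs, i0, i1) {
  lower <- ifelse(i0 > 1L, cs[pmax(i0 - 1L, 1L)], 0)
  cs[i1] - lower
}

#' Windowed LFP feature extraction
#'
#' Evaluates the full 40-feature catalogue ([feature_catalog()]) on 2.5 s
#' windows centred at the requested times: 8 band powers, 4 amplitude
#' covariations, 4 weighted phase-lag indices and 24 phase-amplitude
#' coupling measures. With `centers = NULL` a continuous grid across the
#' whole session (step `step_s`) is used — the windowing convention shared
#' by the network-discovery stage.
#'
#' Band-limited analytic signals are computed once per band over the whole
#' session (zero-phase FIR + Hilbert); windows then reduce per-sample
#' integrand series via cumulative sums, so cost is linear in session
#' length. Windows that would overlap the session edges (including half a
#' filter length of edge trim for the widest filter) are dropped.
#'
#' @param rec A [paired_recording()].
#' @param centers Window-centre times in seconds, or `NULL` for the
#'   continuous session grid.
#' @param window_s Window length in seconds (default 2.5).
#' @param step_s Grid step for `centers = NULL` (default 1.5).
#' @return Tibble with `time` (window centre, s) plus 40 feature columns.
#' @export
session_features <- function(rec, centers = NULL, window_s = 2.5, step_s = 1.5) {
  fs <- rec$fs
  n <- length(rec$hpc)
  sf <- single_freq_bands()
  lowb <- cfc_low_bands()
  highb <- cfc_high_bands()
  all_bands <- c(sf, lowb)
  trim <- max(vapply(all_bands, edge_trim_samples, numeric(1), fs = fs))

  if (is.null(centers)) {
    t_lo <- (trim + 1L) / fs + window_s / 2
    t_hi <- n / fs - trim / fs - window_s / 2
    if (t_hi < t_lo) stop("session too short for any window", call. = FALSE)
    centers <- seq(t_lo, t_hi, by = step_s)
  }
  wi <- window_indices(centers, fs, window_s, n, trim)
  if (!all(wi$ok)) {
    warning(sprintf("%d window(s) outside usable session range dropped",
                    sum(!wi$ok)), call. = FALSE)
  }
  centers <- centers[wi$ok]
  i0 <- wi$i0[wi$ok]; i1 <- wi$i1[wi$ok]
  if (!length(centers)) stop("no valid windows", call. = FALSE)
  wlen <- wi$wlen

  nfft <- next_pow2(n + 2L * (2L * trim + 1L))
  fft_h <- stats::fft(c(rec$hpc, rep(0, nfft - n)))
  fft_p <- stats::fft(c(rec$pfc, rep(0, nfft - n)))

  out <- list(time = centers)
  wmean <- function(v) wsum(cumsum(v), i0, i1) / wlen

  # single-frequency features, one band at a time to bound memory
  for (bn in names(sf)) {
    zh <- band_analytic(rec$hpc, sf[[bn]], fs, x_fft = fft_h, nfft = nfft)
    zp <- band_analytic(rec$pfc, sf[[bn]], fs, x_fft = fft_p, nfft = nfft)
    ah <- Mod(zh); ap <- Mod(zp)
    im <- Im(zh * Conj(zp))
    out[[paste0("pow_hpc_", bn)]] <- wmean(Re(zh)^2)
    out[[paste0("pow_pfc_", bn)]] <- wmean(Re(zp)^2)
    m_ah <- wmean(ah); m_ap <- wmean(ap)
    m_ah2 <- wmean(ah^2); m_ap2 <- wmean(ap^2); m_ahap <- wmean(ah * ap)
    cov_ <- m_ahap - m_ah * m_ap
    v_h <- pmax(m_ah2 - m_ah^2, 0); v_p <- pmax(m_ap2 - m_ap^2, 0)
    denom <- sqrt(v_h * v_p)
    out[[paste0("ampcov_hpcPfc_", bn)]] <- ifelse(denom > 0, cov_ / denom, 0)
    m_im <- wmean(im); m_abs <- wmean(abs(im))
    out[[paste0("wpli_hpcPfc_", bn)]] <- ifelse(m_abs > 0, abs(m_im) / m_abs, 0)
    rm(zh, zp, ah, ap, im)
  }

  # low-band phase unit vectors for cross-frequency coupling
  phase_cos <- list(); phase_sin <- list()
  for (ln in names(lowb)) {
    zh <- band_analytic(rec$hpc, lowb[[ln]], fs, x_fft = fft_h, nfft = nfft)
    ph <- Arg(zh); rm(zh)
    phase_cos[[paste0("hpc", ln)]] <- cos(ph)
    phase_sin[[paste0("hpc", ln)]] <- sin(ph)
    zp <- band_analytic(rec$pfc, lowb[[ln]], fs, x_fft = fft_p, nfft = nfft)
    ph <- Arg(zp); rm(zp)
    phase_cos[[paste0("pfc", ln)]] <- cos(ph)
    phase_sin[[paste0("pfc", ln)]] <- sin(ph)
  }
  ffts <- list(hpc = fft_h, pfc = fft_p)
  rm(fft_h, fft_p)

  for (ar in c("hpc", "pfc")) {
    for (hn in names(highb)) {
      z <- band_analytic(rec[[ar]], highb[[hn]], fs,
                         x_fft = ffts[[ar]], nfft = nfft)
      a <- Mod(z); rm(z)
      s_a <- wsum(cumsum(a), i0, i1)
      for (src in names(phase_cos)) {
        s_re <- wsum(cumsum(a * phase_cos[[src]]), i0, i1)
        s_im <- wsum(cumsum(a * phase_sin[[src]]), i0, i1)
        out[[paste0("cfc_", src, "_", ar, hn)]] <-
          ifelse(s_a > 0, sqrt(s_re^2 + s_im^2) / s_a, 0)
      }
      rm(a)
    }
  }

  res <- tibble::as_tibble(out)
  # order columns per the catalogue
  res[, c("time", feature_catalog()$feature)]
}

#' Event-locked feature grids
#'
#' Evaluates all 40 features on the 11-point event-locked grid (offsets
#' -7.5 ... +7.5 s) for each event time. Events whose grid would leave the
#' usable session range are dropped with a warning.
#'
#' @param rec A [paired_recording()].
#' @param events Event times in seconds (e.g. centre-entry times).
#' @param spec A [dynamic_window_spec()].
#' @return Tibble with columns `run` (event index), `time_rel` (seconds
#'   relative to the event), `time` (absolute) and the 40 features.
#' @export
windowed_features <- function(rec, events, spec = dynamic_window_spec()) {
  fs <- rec$fs
  n <- length(rec$hpc)
  all_bands <- c(single_freq_bands(), cfc_low_bands())
  trim <- max(vapply(all_bands, edge_trim_samples, numeric(1), fs = fs))
  lo_ok <- (trim + 1L) / fs + spec$window_s / 2 + spec$span_s
  hi_ok <- n / fs - trim / fs - spec$window_s / 2 - spec$span_s
  ok <- events >= lo_ok & events <= hi_ok
  if (!all(ok)) {
    warning(sprintf("%d event(s) too close to session edges dropped",
                    sum(!ok)), call. = FALSE)
  }
  events <- events[ok]
  if (!length(events)) stop("no valid events", call. = FALSE)
  grid <- tidyr::expand_grid(run = seq_along(events), time_rel = spec$offsets) |>
    dplyr::mutate(time = events[.data$run] + .data$time_rel)
  feats <- session_features(rec, centers = grid$time, window_s = spec$window_s)
  dplyr::bind_cols(grid[, c("run", "time_rel")], feats)
}

#' Z-score event-locked dynamics within each run
#'
#' Converts each run's 11-point grid to z-scores relative to the rest of
#' that run (mean 0, SD 1 across the grid). Zero-variance runs yield all
#' zeros and are flagged via the `degenerate` attribute.
#'
#' @param x Numeric vector (one run's grid values).
#' @return Z-scored vector of the same length.
#' @export
zscore_run <- function(x) {
  if (length(x) < 2L) stop("need at least 2 grid points", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) return(structure(rep(0, length(x)), degenerate = TRUE))
  (x - mean(x)) / s
}

#' @rdname zscore_run
#' @param data Long tibble with columns `run`, `value` (and any others).
#' @return For `zscore_event_dynamics()`: `data` with `value` z-scored
#'   within each run.
#' @export
zscore_event_dynamics <- function(data) {
  stopifnot(all(c("run", "value") %in% names(data)))
  data |>
    dplyr::group_by(.data$run) |>
    dplyr::mutate(value = as.numeric(zscore_run(.data$value))) |>
    dplyr::ungroup()
}
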