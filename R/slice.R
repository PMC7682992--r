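#' Optically evoked intracellular trace
#'
#' Container for a voltage- or current-clamp sweep with the optogenetic
#' stimulus train (8 Hz flashes in the standard protocol, i.e. 125 ms
#' inter-stimulus intervals).
#'
#' @param value Sampled current (pA) or voltage (mV).
#' @param fs Sampling rate (samples/s).
#' @param stim_times Stimulus onset times (s), strictly inside the trace.
#' @param units `"pA"` (voltage clamp) or `"mV"` (current clamp).
#' @param baseline Two-element window (s) used for baseline subtraction;
#'   defaults to everything before the first stimulus.
#' @return An `evoked_trace` list.
#' @export
evoked_trace <- function(value, fs, stim_times, units = c("pA", "mV"),
                         baseline = NULL) {
  units <- match.arg(units)
  dur <- length(value) / fs
  if (any(stim_times <= 0 | stim_times >= dur)) {
    stop("stimulus times must lie inside the trace", call. = FALSE)
  }
  stim_times <- sort(stim_times)
  baseline <- baseline %||% c(0, stim_times[1])
  structure(
    list(value = value, fs = fs, stim_times = stim_times, units = units,
         baseline = baseline, time = (seq_along(value) - 1) / fs),
    class = "evoked_trace"
  )
}

trace_baseline <- function(trace) {
  sel <- trace$time >= trace$baseline[1] & trace$time < trace$baseline[2]
  if (!any(sel)) stop("empty baseline window", call. = FALSE)
  mean(trace$value[sel])
}

# Default per-pulse response window: the inter-stimulus interval (125 ms
# for the 8 Hz train), which partitions the train without overlap.
default_isi <- function(trace) {
  if (length(trace$stim_times) > 1) {
    min(diff(trace$stim_times))
  } else {
    min(0.125, length(trace$value) / trace$fs - trace$stim_times[1])
  }
}

#' Total evoked charge
#'
#' Integral of the baseline-subtracted current over the response window,
#' reported as a magnitude in pC (1 pA x 1 s = 1 pC; inward currents are
#' negative deflections, and the absolute integral is returned).
#'
#' @param trace An [evoked_trace()] (voltage clamp, pA).
#' @param window Response window `c(t0, t1)` in s; defaults to the span
#'   from the first stimulus to one inter-stimulus interval after the
#'   last.
#' @return Charge magnitude in pC.
#' @export
total_charge <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "evoked_trace"))
  if (trace$units != "pA") stop("charge requires a current (pA) trace", call. = FALSE)
  window <- window %||%
    c(trace$stim_times[1], max(trace$stim_times) + default_isi(trace))
  if (window[1] < 0 || window[2] > length(trace$value) / trace$fs) {
    stop("response window outside trace", call. = FALSE)
  }
  sel <- trace$time >= window[1] & trace$time < window[2]
  abs(sum(trace$value[sel] - trace_baseline(trace)) / trace$fs)
}

# Peak of the baseline-subtracted, noise-robust (1 kHz low-pass) response
# after a stimulus; returns the signed extremum value.
pulse_peak <- function(trace, stim, window_s) {
  sel <- trace$time >= stim & trace$time < stim + window_s
  seg <- trace$value[sel] - trace_baseline(trace)
  if (trace$fs > 2000) {
    bf <- signal::butter(4, 1000 / (trace$fs / 2))
    seg <- signal::filtfilt(bf, seg)
  }
  seg[which.max(abs(seg))]
}

#' Paired-pulse ratio
#'
#' Ratio of the second to the first baseline-subtracted peak response
#' amplitude, an index of short-term synaptic plasticity (< 1 depression,
#' > 1 facilitation). Measurement windows are the inter-stimulus interval,
#' so they never overlap.
#'
#' @param trace An [evoked_trace()].
#' @param stim1,stim2 Indices into `trace$stim_times` (default 1, 2).
#' @return Ratio (attribute `degenerate` if the first peak is zero).
#' @export
paired_pulse_ratio <- function(trace, stim1 = 1, stim2 = 2) {
  stopifnot(inherits(trace, "evoked_trace"),
            length(trace$stim_times) >= max(stim1, stim2))
  isi <- trace$stim_times[stim2] - trace$stim_times[stim1]
  if (isi <= 0) stop("stimuli must be ordered in time", call. = FALSE)
  p1 <- pulse_peak(trace, trace$stim_times[stim1], isi)
  p2 <- pulse_peak(trace, trace$stim_times[stim2], isi)
  if (p1 == 0) return(structure(NA_real_, degenerate = TRUE))
  abs(p2) / abs(p1)
}

#' Latency to the first evoked spike
#'
#' Time from a stimulus to the first upward crossing of the spike
#' threshold (0 mV by default, appropriate for overshooting action
#' potentials) within one inter-stimulus interval. `NA` if no spike.
#'
#' @param trace An [evoked_trace()] (current clamp, mV).
#' @param stim Index into `trace$stim_times` (default 1).
#' @param threshold Crossing threshold in mV (default 0).
#' @return Latency in ms, or `NA_real_`.
#' @export
first_spike_latency <- function(trace, stim = 1, threshold = 0) {
  stopifnot(inherits(trace, "evoked_trace"))
  if (trace$units != "mV") stop("spike latency requires a voltage trace", call. = FALSE)
  t0 <- trace$stim_times[stim]
  sel <- which(trace$time >= t0 & trace$time < t0 + default_isi(trace))
  v <- trace$value[sel]
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  if (!length(up)) return(NA_real_)
  (trace$time[sel[up[1] + 1L]] - t0) * 1000
}

#' Count evoked spikes across the stimulus train
#'
#' Total upward threshold crossings within the inter-stimulus interval of
#' every stimulus, with a refractory deadtime so one action potential is
#' never counted twice.
#'
#' @inheritParams first_spike_latency
#' @param refractory_ms Minimum separation between counted crossings
#'   (default 1 ms).
#' @return Integer spike count.
#' @export
count_evoked_spikes <- function(trace, threshold = 0, refractory_ms = 1) {
  stopifnot(inherits(trace, "evoked_trace"))
  if (trace$units != "mV") stop("spike counting requires a voltage trace", call. = FALSE)
  isi <- default_isi(trace)
  total <- 0L
  for (t0 in trace$stim_times) {
    sel <- which(trace$time >= t0 & trace$time < t0 + isi)
    v <- trace$value[sel]
    up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
    if (!length(up)) next
    times <- trace$time[sel[up + 1L]]
    kept <- times[1]; last <- times[1]
    for (tt in times[-1]) {
      if (tt - last >= refractory_ms / 1000) { kept <- c(kept, tt); last <- tt }
    }
    total <- total + length(kept)
  }
  total
}

#' Intrinsic properties from a current-step protocol
#'
#' Helper computations on a hyperpolarizing step sweep: resting membrane
#' potential (pre-step mean) and input resistance (steady-state voltage
#' deflection over injected current).
#'
#' @param value Voltage sweep (mV).
#' @param fs Sampling rate (samples/s).
#' @param step_window Step onset/offset times (s).
#' @param current_pA Injected current (pA, nonzero).
#' @return Tibble with `resting_mV` and `input_resistance_MOhm`.
#' @export
intrinsic_properties <- function(value, fs, step_window, current_pA) {
  stopifnot(current_pA != 0, length(step_window) == 2)
  t <- (seq_along(value) - 1) / fs
  rest <- mean(value[t < step_window[1]])
  steady <- mean(value[t >= step_window[1] + 0.6 * diff(step_window) &
                         t < step_window[2]])
  tibble::tibble(
    resting_mV = rest,
    input_resistance_MOhm = (steady - rest) / current_pA * 1000
  )
}
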