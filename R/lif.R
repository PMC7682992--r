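#' Circuit parameters for the feedforward-inhibition model
#'
#' Two leaky integrate-and-fire cells — a pyramidal output cell and a
#' fast-spiking interneuron (FSIN) that inhibits it — receive the same two
#' Poisson inputs (rhythmic "hippocampal" and constant-rate "noise").
#' Synaptic decay constants are 8 ms (excitation) and 20 ms (inhibition),
#' reflecting the longer timescale of synaptic inhibition. The remaining
#' constants (membrane time constant 20 ms, threshold 1 and reset 0 in
#' dimensionless potential units, 2 ms refractory period, 0.1 ms step) are
#' conventional defaults, all configurable. An optional
#' interneuron-selective interneuron (ISI) receives the same feedforward
#' excitation and inhibits the FSIN (the disinhibition variant); its
#' weights default to 0, which reduces the circuit to the two-cell model
#' exactly.
#'
#' @param tau_m Membrane time constant, ms.
#' @param tau_e,tau_i Excitatory / inhibitory synaptic decay, ms.
#' @param v_thresh,v_reset Spike threshold and reset (dimensionless).
#' @param refrac_ms Absolute refractory period, ms.
#' @param dt_ms Integration step, ms (must be < min(tau_e, tau_m)/5).
#' @param w_hpc_pyr,w_noise_pyr Input weights onto the pyramidal cell.
#' @param w_hpc_fsin,w_noise_fsin Input weights onto the FSIN (the swept
#'   feedforward drive).
#' @param w_fsin_pyr FSIN -> pyramidal weight (must be <= 0).
#' @param w_hpc_isi,w_noise_isi,w_isi_fsin Disinhibition-motif weights
#'   (`w_isi_fsin` <= 0).
#' @return A `circuit_params` list.
#' @export
circuit_params <- function(tau_m = 20, tau_e = 8, tau_i = 20,
                           v_thresh = 1, v_reset = 0, refrac_ms = 2,
                           dt_ms = 0.1,
                           w_hpc_pyr = 0.02, w_noise_pyr = 0.02,
                           w_hpc_fsin = 0.02, w_noise_fsin = 0.02,
                           w_fsin_pyr = -0.05,
                           w_hpc_isi = 0, w_noise_isi = 0, w_isi_fsin = 0) {
  if (tau_e <= 0 || tau_i <= 0 || tau_m <= 0) {
    stop("time constants must be positive", call. = FALSE)
  }
  if (dt_ms >= min(tau_e, tau_m) / 5) {
    stop("dt_ms too coarse: must be < min(tau_e, tau_m)/5", call. = FALSE)
  }
  if (w_fsin_pyr > 0 || w_isi_fsin > 0) {
    stop("inhibitory weights must be <= 0", call. = FALSE)
  }
  structure(
    list(
      tau_m = tau_m, tau_e = tau_e, tau_i = tau_i,
      v_thresh = v_thresh, v_reset = v_reset, refrac_ms = refrac_ms,
      dt_ms = dt_ms,
      w_hpc_pyr = w_hpc_pyr, w_noise_pyr = w_noise_pyr,
      w_hpc_fsin = w_hpc_fsin, w_noise_fsin = w_noise_fsin,
      w_fsin_pyr = w_fsin_pyr,
      w_hpc_isi = w_hpc_isi, w_noise_isi = w_noise_isi,
      w_isi_fsin = w_isi_fsin
    ),
    class = "circuit_params"
  )
}

#' Input regime for the feedforward-inhibition model
#'
#' Hippocampal input is an inhomogeneous Poisson process with rate
#' `(rate_max / 2) * (1 - cos(2 pi f t))` — varying sinusoidally between 0
#' and `rate_max` (100 Hz) at the theta frequency `f` (8 Hz), starting at
#' the rate minimum. Noise input is a homogeneous Poisson process at the
#' midpoint rate (50 Hz). Trials are 1 s, and rate/correlation estimates
#' average over `iterations` (1000) independent trials.
#'
#' @param rate_max Peak hippocampal rate, Hz.
#' @param f Modulation frequency, Hz.
#' @param noise_rate Constant noise rate, Hz.
#' @param duration_s Trial length, s.
#' @param iterations Number of trials to average.
#' @return An `input_spec` list.
#' @export
input_spec <- function(rate_max = 100, f = 8, noise_rate = 50,
                       duration_s = 1, iterations = 1000) {
  stopifnot(rate_max >= 0, noise_rate >= 0, f > 0, duration_s > 0,
            iterations >= 1)
  structure(
    list(rate_max = rate_max, f = f, noise_rate = noise_rate,
         duration_s = duration_s, iterations = as.integer(iterations)),
    class = "input_spec"
  )
}

hpc_rate_fn <- function(spec) {
  function(t) (spec$rate_max / 2) * (1 - cos(2 * pi * spec$f * t))
}

#' Inhomogeneous Poisson spike train
#'
#' Bin-Bernoulli generation: in each step of width `dt_ms` a spike occurs
#' with probability `rate(t) * dt`. Requires `rate * dt < 0.2` everywhere
#' (refine `dt_ms` otherwise).
#'
#' @param rate A rate function of time (s) returning Hz, or a single
#'   constant rate in Hz.
#' @param duration_s Train length, s.
#' @param dt_ms Bin width, ms.
#' @return Numeric vector of spike times (s). The per-bin 0/1 counts are
#'   available via attribute `bins`.
#' @export
inhomogeneous_poisson <- function(rate, duration_s, dt_ms = 0.1) {
  n <- round(duration_s * 1000 / dt_ms)
  t <- (seq_len(n) - 0.5) * dt_ms / 1000
  r <- if (is.function(rate)) rate(t) else rep(rate, n)
  if (any(!is.finite(r)) || any(r < 0)) stop("rate must be >= 0", call. = FALSE)
  p <- r * dt_ms / 1000
  if (any(p >= 0.2)) stop("rate * dt too large; refine dt_ms", call. = FALSE)
  bins <- as.integer(stats::runif(n) < p)
  structure(t[bins == 1L], bins = bins)
}

# One trial's input realization as per-bin counts.
draw_inputs <- function(spec, dt_ms) {
  hpc <- inhomogeneous_poisson(hpc_rate_fn(spec), spec$duration_s, dt_ms)
  noise <- inhomogeneous_poisson(spec$noise_rate, spec$duration_s, dt_ms)
  list(hpc = attr(hpc, "bins"), noise = attr(noise, "bins"))
}

#' Simulate the feedforward-inhibition circuit
#'
#' Runs the per-dt leaky integrate-and-fire dynamics (compiled core) on one
#' realization of the two input trains. Both cells (three with the
#' disinhibition motif) receive the same inputs; each input spike
#' increments an exponentially decaying synaptic drive, the membrane
#' integrates toward it with time constant `tau_m`, threshold crossings
#' emit spikes, reset the potential and enforce the refractory period.
#'
#' @param params A [circuit_params()].
#' @param hpc_bins,noise_bins Integer per-bin spike counts (from
#'   [inhomogeneous_poisson()] bins), equal length.
#' @param reference Use the plain-R per-dt reference loop instead of the
#'   compiled core (slow; for validation).
#' @return List of spike times in seconds: `pyr`, `fsin`, `isi`.
#' @export
simulate_circuit <- function(params, hpc_bins, noise_bins, reference = FALSE) {
  stopifnot(inherits(params, "circuit_params"))
  sim <- if (reference) lif_simulate_ref else lif_simulate_cpp
  out <- sim(as.integer(hpc_bins), as.integer(noise_bins), unclass(params))
  lapply(out, function(idx) (idx - 0.5) * params$dt_ms / 1000)
}

# Plain-R per-dt reference integrator; mirrors src/lif.cpp statement for
# statement and serves as the independent oracle for the compiled core.
lif_simulate_ref <- function(hpc, noise, p) {
  n <- length(hpc)
  stopifnot(length(noise) == n)
  dt <- p$dt_ms
  de <- exp(-dt / p$tau_e); di <- exp(-dt / p$tau_i); a <- dt / p$tau_m
  refrac <- ceiling(p$refrac_ms / dt)
  e_pyr <- e_fsin <- e_isi <- 0
  i_pyr <- i_fsin <- 0
  v_pyr <- v_fsin <- v_isi <- 0
  r_pyr <- r_fsin <- r_isi <- 0L
  s_fsin_prev <- s_isi_prev <- 0L
  sp_pyr <- integer(); sp_fsin <- integer(); sp_isi <- integer()
  for (t in seq_len(n)) {
    nh <- hpc[t]; nn <- noise[t]
    e_isi <- e_isi * de + p$w_hpc_isi * nh + p$w_noise_isi * nn
    e_fsin <- e_fsin * de + p$w_hpc_fsin * nh + p$w_noise_fsin * nn
    e_pyr <- e_pyr * de + p$w_hpc_pyr * nh + p$w_noise_pyr * nn
    i_fsin <- i_fsin * di + p$w_isi_fsin * s_isi_prev
    i_pyr <- i_pyr * di + p$w_fsin_pyr * s_fsin_prev
    s_isi <- 0L; s_fsin <- 0L
    if (r_isi > 0L) { r_isi <- r_isi - 1L; v_isi <- p$v_reset } else {
      v_isi <- v_isi + a * (-v_isi + e_isi)
      if (v_isi >= p$v_thresh) {
        s_isi <- 1L; sp_isi <- c(sp_isi, t); v_isi <- p$v_reset; r_isi <- refrac
      }
    }
    if (r_fsin > 0L) { r_fsin <- r_fsin - 1L; v_fsin <- p$v_reset } else {
      v_fsin <- v_fsin + a * (-v_fsin + e_fsin + i_fsin)
      if (v_fsin >= p$v_thresh) {
        s_fsin <- 1L; sp_fsin <- c(sp_fsin, t); v_fsin <- p$v_reset
        r_fsin <- refrac
      }
    }
    if (r_pyr > 0L) { r_pyr <- r_pyr - 1L; v_pyr <- p$v_reset } else {
      v_pyr <- v_pyr + a * (-v_pyr + e_pyr + i_pyr)
      if (v_pyr >= p$v_thresh) {
        sp_pyr <- c(sp_pyr, t); v_pyr <- p$v_reset; r_pyr <- refrac
      }
    }
    s_isi_prev <- s_isi; s_fsin_prev <- s_fsin
  }
  list(pyr = sp_pyr, fsin = sp_fsin, isi = sp_isi)
}

#' Pearson correlation of binned spike trains
#'
#' Bins both trains at `bin_ms` (default 10 ms, resolving theta-cycle
#' structure) over a common duration and correlates the counts. Returns 0
#' with attribute `degenerate` if either count vector has zero variance.
#'
#' @param a,b Spike-time vectors (s).
#' @param duration_s Common duration, s.
#' @param bin_ms Bin width, ms.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
binned_correlation <- function(a, b, duration_s, bin_ms = 10) {
  breaks <- seq(0, duration_s, by = bin_ms / 1000)
  ca <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE),
                 nbins = length(breaks) - 1L)
  cb <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE),
                 nbins = length(breaks) - 1L)
  if (stats::sd(ca) == 0 || stats::sd(cb) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  stats::cor(ca, cb)
}

# Mean rates and input-output correlations over `iterations` trials.
# Correlations are computed per trial then averaged (the concatenated-bin
# alternative is available via `concat = TRUE`).
run_trials <- function(params, spec, seed, iterations = spec$iterations,
                       bin_ms = 10, concat = FALSE) {
  res <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(iterations), function(i) {
      inp <- draw_inputs(spec, params$dt_ms)
      st <- simulate_circuit(params, inp$hpc, inp$noise)
      hpc_t <- (which(inp$hpc == 1L) - 0.5) * params$dt_ms / 1000
      noise_t <- (which(inp$noise == 1L) - 0.5) * params$dt_ms / 1000
      tibble::tibble(
        rate_pyr = length(st$pyr) / spec$duration_s,
        rate_fsin = length(st$fsin) / spec$duration_s,
        corr_hpc = as.numeric(
          binned_correlation(st$pyr, hpc_t, spec$duration_s, bin_ms)),
        corr_noise = as.numeric(
          binned_correlation(st$pyr, noise_t, spec$duration_s, bin_ms))
      )
    })
  })
  dplyr::bind_rows(res)
}

summarize_trials <- function(tr) {
  se <- function(x) stats::sd(x) / sqrt(length(x))
  tibble::tibble(
    rate_pyr = mean(tr$rate_pyr), se_rate_pyr = se(tr$rate_pyr),
    rate_fsin = mean(tr$rate_fsin), se_rate_fsin = se(tr$rate_fsin),
    corr_hpc = mean(tr$corr_hpc), se_corr_hpc = se(tr$corr_hpc),
    corr_noise = mean(tr$corr_noise), se_corr_noise = se(tr$corr_noise),
    snr = mean(tr$corr_hpc) / mean(tr$corr_noise)
  )
}

#' Calibrate the circuit to its standard operating point
#'
#' Finds weights such that, under the standard input regime, the FSIN
#' fires at `targets["fsin"]` (~20 Hz), the pyramidal cell at
#' `targets["pyr_inh"]` (~25 Hz) with inhibition intact, and at
#' `targets["pyr_noinh"]` (~50 Hz) with the inhibitory weight zeroed.
#' Because each rate is monotone in the corresponding weight, the search
#' is three coordinate bisections (common random numbers across candidate
#' weights make each bisected function deterministic): the shared
#' excitatory weight onto the pyramidal cell (no-inhibition rate), the
#' shared excitatory weight onto the FSIN, then the magnitude of the
#' FSIN-to-pyramidal weight. A target set with
#' `pyr_inh > pyr_noinh` is rejected: feedforward inhibition cannot raise
#' the pyramidal rate in this architecture.
#'
#' @param targets Named vector: `fsin`, `pyr_inh`, `pyr_noinh` (Hz).
#' @param spec An [input_spec()].
#' @param base A [circuit_params()] template.
#' @param seed Seed for the calibration trials.
#' @param reps Trials per candidate evaluation (default 40).
#' @param tol Relative rate tolerance (default 0.1).
#' @param w_max Upper weight-magnitude bound for the bracket search.
#' @return A `lif_calibration`: list with `params`, `achieved` (rates at
#'   `reps` trials), `targets`, `feasible`, `detail`.
#' @export
calibrate_operating_point <- function(targets = c(fsin = 20, pyr_inh = 25,
                                                  pyr_noinh = 50),
                                      spec = input_spec(),
                                      base = circuit_params(),
                                      seed = 1L, reps = 40,
                                      tol = 0.1, w_max = 10) {
  stopifnot(all(c("fsin", "pyr_inh", "pyr_noinh") %in% names(targets)))
  if (targets["pyr_inh"] > targets["pyr_noinh"]) {
    stop("infeasible targets: inhibition cannot raise the pyramidal rate",
         call. = FALSE)
  }
  if (all(targets == 0)) {
    p <- modify_params(base, w_hpc_pyr = 0, w_noise_pyr = 0,
                       w_hpc_fsin = 0, w_noise_fsin = 0, w_fsin_pyr = 0)
    return(structure(list(params = p,
                          achieved = c(fsin = 0, pyr_inh = 0, pyr_noinh = 0),
                          targets = targets, feasible = TRUE,
                          detail = "all-zero targets: zero weights"),
                     class = "lif_calibration"))
  }

  rate_of <- function(params, cell) {
    tr <- run_trials(params, spec, seed = seed, iterations = reps)
    mean(tr[[paste0("rate_", cell)]])
  }
  bisect_weight <- function(f, target, lo = 0, hi = w_max, iters = 40) {
    # f monotone nondecreasing in the weight (common random numbers)
    if (f(hi) < target) return(NA_real_)
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (f(mid) < target) lo <- mid else hi <- mid
      if ((hi - lo) < 1e-5 * w_max) break
    }
    (lo + hi) / 2
  }

  # 1. excitatory drive onto the pyramidal cell: no-inhibition rate
  f_pyr <- function(w) rate_of(modify_params(base, w_hpc_pyr = w,
                                             w_noise_pyr = w,
                                             w_fsin_pyr = 0), "pyr")
  w_pyr <- bisect_weight(f_pyr, targets["pyr_noinh"])
  # 2. excitatory drive onto the FSIN (FSIN receives no inhibition here)
  f_fsin <- function(w) rate_of(modify_params(base, w_hpc_fsin = w,
                                              w_noise_fsin = w), "fsin")
  w_fsin <- bisect_weight(f_fsin, targets["fsin"])
  # 3. inhibitory weight magnitude: pyramidal rate decreases with it
  w_inh <- NA_real_
  if (!is.na(w_pyr) && !is.na(w_fsin)) {
    f_inh <- function(wm) -rate_of(modify_params(base,
                                                 w_hpc_pyr = w_pyr, w_noise_pyr = w_pyr,
                                                 w_hpc_fsin = w_fsin, w_noise_fsin = w_fsin,
                                                 w_fsin_pyr = -wm), "pyr")
    w_inh <- bisect_weight(f_inh, -targets["pyr_inh"], hi = 5 * w_max)
  }
  if (anyNA(c(w_pyr, w_fsin, w_inh))) {
    return(structure(list(params = NULL, achieved = NULL, targets = targets,
                          feasible = FALSE,
                          detail = "no weight within bounds reaches a target rate"),
                     class = "lif_calibration"))
  }
  params <- modify_params(base,
                          w_hpc_pyr = w_pyr, w_noise_pyr = w_pyr,
                          w_hpc_fsin = w_fsin, w_noise_fsin = w_fsin,
                          w_fsin_pyr = -w_inh)
  achieved <- c(
    fsin = rate_of(params, "fsin"),
    pyr_inh = rate_of(params, "pyr"),
    pyr_noinh = rate_of(modify_params(params, w_fsin_pyr = 0), "pyr")
  )
  rel <- abs(achieved - targets[names(achieved)]) /
    pmax(targets[names(achieved)], 1e-9)
  feasible <- all(rel <= tol | targets[names(achieved)] == 0)
  structure(
    list(params = params, achieved = achieved, targets = targets,
         feasible = feasible,
         detail = sprintf("relative errors: %s",
                          paste(sprintf("%s %.1f%%", names(rel), 100 * rel),
                                collapse = ", "))),
    class = "lif_calibration"
  )
}

modify_params <- function(params, ...) {
  upd <- list(...)
  p <- unclass(params)
  p[names(upd)] <- upd
  do.call(circuit_params, p)
}

#' @export
print.lif_calibration <- function(x, ...) {
  cat("<lif_calibration>\n")
  if (!is.null(x$achieved)) {
    cat(sprintf("  fsin %.1f Hz (target %g), pyr %.1f Hz (target %g), pyr w/o inhibition %.1f Hz (target %g)\n",
                x$achieved["fsin"], x$targets["fsin"],
                x$achieved["pyr_inh"], x$targets["pyr_inh"],
                x$achieved["pyr_noinh"], x$targets["pyr_noinh"]))
  }
  cat(sprintf("  feasible: %s (%s)\n", x$feasible, x$detail))
  invisible(x)
}

#' Sweep the feedforward drive onto the FSIN
#'
#' Scales the two excitatory weights onto the FSIN together (default) or
#' the hippocampal weight only, across a grid of multiples of the
#' calibrated drive, and at each grid point averages rates, the
#' correlation of pyramidal output with each input train, and their ratio
#' (the signal-to-noise ratio) over `reps` trials.
#'
#' @param params Calibrated [circuit_params()] (e.g.
#'   `calibrate_operating_point(...)$params`).
#' @param spec An [input_spec()].
#' @param grid Drive multipliers (default 0 to 2x in 11 steps).
#' @param reps Trials per grid point (default `spec$iterations`).
#' @param seed Base seed; trials reuse the same seed across grid points
#'   (common random numbers).
#' @param mode `"parallel"` (both weights) or `"hpc_only"`.
#' @param bin_ms Correlation bin width, ms.
#' @return A `lif_sweep` tibble: `drive`, `rate_pyr`, `rate_fsin`,
#'   `corr_hpc`, `corr_noise`, `snr` and standard errors.
#' @export
sweep_fsin_drive <- function(params, spec = input_spec(),
                             grid = seq(0, 2, length.out = 11),
                             reps = spec$iterations, seed = 1L,
                             mode = c("parallel", "hpc_only"),
                             bin_ms = 10) {
  mode <- match.arg(mode)
  if (!length(grid)) stop("empty drive grid", call. = FALSE)
  rows <- purrr::map(grid, function(g) {
    p <- if (mode == "parallel") {
      modify_params(params, w_hpc_fsin = g * params$w_hpc_fsin,
                    w_noise_fsin = g * params$w_noise_fsin)
    } else {
      modify_params(params, w_hpc_fsin = g * params$w_hpc_fsin)
    }
    tr <- run_trials(p, spec, seed = seed, iterations = reps, bin_ms = bin_ms)
    dplyr::bind_cols(tibble::tibble(drive = g), summarize_trials(tr))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lif_sweep", class(out))
  attr(out, "mode") <- mode
  out
}

#' Disinhibition variant of the drive sweep
#'
#' Adds an interneuron-selective interneuron receiving the same
#' feedforward excitation and inhibiting the FSIN, then runs the same
#' drive sweep. With all ISI weights zero the result is identical to the
#' base model under the same seed.
#'
#' @inheritParams sweep_fsin_drive
#' @param w_isi Excitatory weight onto the ISI (both inputs).
#' @param w_isi_fsin ISI -> FSIN inhibitory weight (<= 0).
#' @return A `lif_sweep` tibble.
#' @export
disinhibition_variant <- function(params, spec = input_spec(),
                                  grid = seq(0, 2, length.out = 11),
                                  w_isi = 0, w_isi_fsin = 0,
                                  reps = spec$iterations, seed = 1L,
                                  bin_ms = 10) {
  p <- modify_params(params, w_hpc_isi = w_isi, w_noise_isi = w_isi,
                     w_isi_fsin = w_isi_fsin)
  sweep_fsin_drive(p, spec, grid = grid, reps = reps, seed = seed,
                   bin_ms = bin_ms)
}

#' Signal-to-noise ratio versus input modulation frequency
#'
#' Holds the calibrated circuit fixed and varies the frequency at which
#' the hippocampal input rate is modulated, reporting the SNR (ratio of
#' pyramidal-output correlation with the hippocampal vs noise input) at
#' each frequency. Theta-range modulation is expected to transmit best.
#'
#' @param f_values Modulation frequencies, Hz.
#' @inheritParams sweep_fsin_drive
#' @return Tibble `f`, `snr`, plus rate and correlation columns.
#' @export
frequency_sweep <- function(params, spec = input_spec(),
                            f_values = c(1, 2, 4, 8, 16, 24, 40),
                            reps = spec$iterations, seed = 1L, bin_ms = 10) {
  if (any(f_values <= 0)) stop("modulation frequencies must be > 0", call. = FALSE)
  rows <- purrr::map(f_values, function(f) {
    sp <- spec; sp$f <- f
    tr <- run_trials(params, sp, seed = seed, iterations = reps,
                     bin_ms = bin_ms)
    dplyr::bind_cols(tibble::tibble(f = f), summarize_trials(tr))
  })
  dplyr::bind_rows(rows)
}
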