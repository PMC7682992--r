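#' Synthetic session configuration
#'
#' Parameters of the paired-LFP + trajectory generator. Defaults emulate
#' the study conditions: 15-minute sessions sampled at 2000 Hz, a
#' hippocampal theta rhythm at 8 Hz riding on a 1/f background, a fraction
#' `coupling_strength` of the theta rhythm shared between channels with the
#' prefrontal copy delayed by `phase_lag` radians (positive = hippocampus
#' leads), and beta/gamma carriers whose amplitude is modulated by the
#' hippocampal theta phase with depth `cfc_depth`. Around each centre entry
#' the coupling and modulation depth ramp up by `approach_gain` (linear
#' rise over the 3 s before entry, linear decay over 1.5 s after).
#'
#' @param fs Sampling rate, samples/s (default 2000).
#' @param duration_s Session length, s (default 900; one 15-min session).
#' @param theta_freq Theta frequency, Hz (default 8).
#' @param theta_snr Height of the hippocampal theta peak over the 1/f
#'   floor (dimensionless, default 6).
#' @param coupling_strength Fraction of theta power shared between the
#'   channels, in `[0, 1]` (default 0.6).
#' @param phase_lag Theta phase lag of the prefrontal copy, radians
#'   (default `pi / 4`; positive = hippocampus leads).
#' @param cfc_depth Modulation depth `m` of high-band amplitude by theta
#'   phase, in `[0, 1]` (default 0.45).
#' @param approach_gain Multiplicative boost of `coupling_strength` and
#'   `cfc_depth` at centre approaches (1 = no event modulation; the WT
#'   default 2.2 ramps the modulation depth to its ceiling at entry).
#' @param coupling_scale Global multiplier on `coupling_strength` and
#'   `cfc_depth` (the heterozygote baseline deficit uses 0.6).
#' @param noise_exponent Spectral exponent of the 1/f background
#'   (default 1).
#' @param coupling_wander SD of a slow (~0.02-0.08 Hz) random modulation of
#'   the coupling strength and modulation depth, for sessions with
#'   genuinely time-varying coupling (default 0 = stationary baseline).
#' @param high_amp Amplitude of the beta/gamma carriers relative to the
#'   unit-variance background: a scalar or one value per band
#'   (beta, low gamma, high gamma; default 0.8).
#' @param open_frac_target Target open-arm occupancy fraction for the
#'   trajectory generator, in `[0, 1]`.
#' @param track_fs Tracking sample rate, Hz (default 30).
#' @param seed Integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(fs = 2000, duration_s = 900, theta_freq = 8,
                         theta_snr = 6, coupling_strength = 0.6,
                         phase_lag = pi / 4, cfc_depth = 0.45,
                         approach_gain = 2.2, coupling_scale = 1,
                         noise_exponent = 1, coupling_wander = 0,
                         high_amp = 0.8, open_frac_target = 0.15,
                         track_fs = 30, seed = 1L) {
  cfg <- list(
    fs = fs, duration_s = duration_s, theta_freq = theta_freq,
    theta_snr = theta_snr, coupling_strength = coupling_strength,
    phase_lag = phase_lag, cfc_depth = cfc_depth,
    approach_gain = approach_gain, coupling_scale = coupling_scale,
    noise_exponent = noise_exponent, coupling_wander = coupling_wander,
    high_amp = high_amp, open_frac_target = open_frac_target,
    track_fs = track_fs, seed = as.integer(seed)
  )
  vals <- unlist(cfg[!(names(cfg) %in% "seed")])
  if (!all(is.finite(vals))) stop("config values must be finite", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (coupling_strength < 0 || coupling_strength > 1) {
    stop("coupling_strength must lie in [0, 1]", call. = FALSE)
  }
  if (cfc_depth < 0 || cfc_depth > 1) {
    stop("cfc_depth must lie in [0, 1]", call. = FALSE)
  }
  if (!length(high_amp) %in% c(1L, 3L)) {
    stop("high_amp must have length 1 or 3", call. = FALSE)
  }
  if (open_frac_target < 0 || open_frac_target > 1) {
    stop("open_frac_target must lie in [0, 1]", call. = FALSE)
  }
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-9) {
    stop("duration_s * fs must be an integer sample count", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# Complex narrowband Gaussian process: white noise restricted to
# [lo, hi] Hz, returned as its analytic signal with the real part scaled
# to unit variance. A band-limited noise process (rather than a pure or
# phase-drifting sinusoid) has uniform phase coverage, a naturally
# fluctuating Hilbert envelope, and a coherence time of ~1/bandwidth, so
# synchrony estimated on independent draws decays properly.
narrowband_z <- function(n, lo, hi, fs) {
  z <- band_analytic(stats::rnorm(n), band_spec("nb", lo, hi), fs)
  s <- stats::sd(Re(z))
  if (!is.finite(s) || s < 1e-12) return(complex(n))  # degenerately slow band
  z / s
}

# 1/f^alpha background, unit variance, via spectral shaping of white noise.
one_over_f_noise <- function(n, fs, exponent = 1, f_lo = 1) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  g <- ifelse(f < f_lo, 0, f^(-exponent / 2))
  x <- Re(stats::fft(X * g, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Event-locked gain profile: 0 away from events, rising linearly from
# (entry - rise_s) to 1 at entry, decaying linearly to 0 over decay_s.
approach_ramp <- function(t, events, rise_s = 3, decay_s = 1.5) {
  ramp <- numeric(length(t))
  for (ev in events) {
    up <- (t - (ev - rise_s)) / rise_s
    down <- 1 - (t - ev) / decay_s
    prof <- pmin(pmax(pmin(up, down), 0), 1)
    ramp <- pmax(ramp, prof)
  }
  ramp
}

#' Generate a paired LFP recording with known ground truth
#'
#' Both channels are a 1/f background plus a narrowband theta rhythm, a
#' fraction of which (the per-sample coupling trace) is shared between the
#' channels with the prefrontal copy phase-delayed, plus beta / low-gamma /
#' high-gamma carriers whose amplitudes are modulated by the hippocampal
#' theta phase (per-sample depth trace). Around each event time both the
#' coupling and the modulation depth ramp up by `approach_gain`.
#'
#' @param config A [synth_config()].
#' @param events Centre-entry times (s) at which coupling ramps; empty for
#'   a stationary session (e.g. home cage).
#' @param id Session identifier.
#' @param genotype Genotype label carried through to the recording.
#' @return List with elements `recording` (a [paired_recording()]) and
#'   `truth` (per-sample `coupling`, `cfc_depth`, plus `events`).
#' @export
generate_lfp_pair <- function(config, events = numeric(0), id = "session",
                              genotype = NA_character_) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    n <- as.integer(round(config$duration_s * config$fs))
    fs <- config$fs
    t <- (seq_len(n) - 1) / fs

    ramp <- approach_ramp(t, events)
    gain <- 1 + (config$approach_gain - 1) * ramp
    wander <- if (config$coupling_wander > 0) {
      config$coupling_wander * Re(narrowband_z(n, 0.02, 0.08, fs))
    } else {
      0
    }
    coupling <- pmin(pmax(
      (config$coupling_strength + wander) * config$coupling_scale * gain, 0), 1)
    m_trace <- pmin(pmax(
      (config$cfc_depth + wander) * config$coupling_scale * gain, 0), 1)

    # independent per-channel delta/low-theta rhythm (2.5-5.5 Hz): gives
    # the low-frequency phase bands genuine, steadily rotating content
    delta_h <- 0.45 * Re(narrowband_z(n, 2.5, 5.5, fs))
    delta_p <- 0.45 * Re(narrowband_z(n, 2.5, 5.5, fs))

    # slow per-channel state factors (arousal-like drifts, 0.02-0.1 Hz):
    # independent gain on each channel's theta amplitude and on its
    # beta/gamma carriers, unrelated to genotype or behaviour
    slow_gain <- function(depth) {
      1 + depth * pmax(pmin(Re(narrowband_z(n, 0.02, 0.1, fs)), 2.5), -2.5)
    }
    theta_gain_h <- slow_gain(0.25)
    theta_gain_p <- slow_gain(0.25)
    carrier_gain_h <- slow_gain(0.3)
    carrier_gain_p <- slow_gain(0.3)

    # theta rhythm: shared + per-channel band-limited noise components
    f0 <- config$theta_freq
    z_s <- narrowband_z(n, f0 - 1.5, f0 + 1.5, fs)
    z_1 <- narrowband_z(n, f0 - 1.5, f0 + 1.5, fs)
    z_2 <- narrowband_z(n, f0 - 1.5, f0 + 1.5, fs)
    a_theta <- 0.3 * sqrt(config$theta_snr)
    theta_h <- a_theta * (sqrt(coupling) * Re(z_s) +
                            sqrt(1 - coupling) * Re(z_1))
    theta_p <- a_theta * (sqrt(coupling) * Re(z_s * exp(-1i * config$phase_lag)) +
                            sqrt(1 - coupling) * Re(z_2))
    phi_shared <- Arg(z_s)

    # beta / low-gamma / high-gamma carriers, independent per channel,
    # amplitude-modulated by the shared theta phase. Each band sums two
    # independent narrowband components, smoothing the envelope so the
    # coupling statistics are not dominated by single-component Rayleigh
    # fluctuations; carrier sub-bands keep most of the +/- theta AM
    # sidebands inside the measurement bands.
    carriers <- list(c(17, 27), c(36, 48), c(74, 90))
    amps <- rep(config$high_amp, length.out = 3)
    high <- function() {
      x <- numeric(n)
      for (j in seq_along(carriers)) {
        cb <- carriers[[j]]
        carrier <- (Re(narrowband_z(n, cb[1], cb[2], fs)) +
                      Re(narrowband_z(n, cb[1], cb[2], fs))) / sqrt(2)
        x <- x + amps[j] * (1 + m_trace * cos(phi_shared)) * carrier
      }
      x
    }
    hpc <- theta_gain_h * theta_h + delta_h + carrier_gain_h * high() +
      one_over_f_noise(n, fs, config$noise_exponent)
    pfc <- theta_gain_p * theta_p + delta_p + carrier_gain_p * high() +
      one_over_f_noise(n, fs, config$noise_exponent)

    list(
      recording = paired_recording(hpc, pfc, fs, id = id, genotype = genotype),
      truth = list(coupling = coupling, cfc_depth = m_trace, events = events,
                   genotype = genotype)
    )
  })
}

#' Generate an elevated-plus-maze trajectory
#'
#' A continuous zone-bout random walk starting in the centre: the animal
#' alternates closed-arm, centre and open-arm bouts, with an occupancy
#' controller steering the realized open-arm fraction toward
#' `config$open_frac_target`. Positions move along arm centrelines with
#' jitter at mouse-like speeds, so every zone transition passes through the
#' centre and the labelled track round-trips through [classify_zones()].
#' Sessions of default length yield well over five closed-to-centre
#' approaches.
#'
#' @param config A [synth_config()].
#' @param geometry An [epm_geometry()].
#' @return List with `track` (tibble `time_s`, `x_cm`, `y_cm`) and
#'   `events` (centre-entry times, s).
#' @export
generate_epm_session <- function(config, geometry = epm_geometry()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed + 1L, {
    fs <- config$track_fs
    n_total <- round(config$duration_s * fs)
    half <- geometry$center_cm / 2
    reach <- half + geometry$arm_length_cm - 0.5
    open_arms <- if (geometry$open_axis == "x") c("E", "W") else c("N", "S")
    closed_arms <- setdiff(c("E", "W", "N", "S"), open_arms)
    arm_dir <- list(E = c(1, 0), W = c(-1, 0), N = c(0, 1), S = c(0, -1))
    open_ax <- if (geometry$open_axis == "x") 1L else 2L

    rtrunc_exp <- function(mean, lo, hi) min(max(stats::rexp(1, 1 / mean), lo), hi)

    # keep the point on the plus-shaped footprint: when both coordinates
    # are beyond the centre square, pull the smaller one back into the arm
    clamp_footprint <- function(p) {
      p <- pmin(pmax(p, -reach), reach)
      if (abs(p[1]) > half && abs(p[2]) > half) {
        j <- if (abs(p[1]) < abs(p[2])) 1L else 2L
        p[j] <- sign(p[j]) * (half - 0.2)
      }
      p
    }

    xs <- numeric(n_total); ys <- numeric(n_total)
    pos <- c(0, 0)
    open_samples <- 0L
    current <- "center"
    dwell <- stats::runif(1, 1, 2.5)
    bout_end <- dwell
    jitter_sd <- 0.6 / sqrt(fs)
    speed <- 12 / fs                          # cm per sample at 12 cm/s
    anchor <- c(0, 0)

    new_anchor <- function(zone) {
      if (zone == "center") {
        stats::runif(2, -half + 0.5, half - 0.5)
      } else {
        d <- arm_dir[[zone]]
        a <- d * stats::runif(1, half + 2, half + geometry$arm_length_cm * 0.7)
        a[abs(d) == 0] <- stats::runif(1, -(half - 0.5), half - 0.5)
        a
      }
    }

    for (i in seq_len(n_total)) {
      t_now <- (i - 1) / fs
      if (t_now >= bout_end) {
        if (current == "center") {
          frac <- open_samples / i
          explore_open <- config$open_frac_target > 0 &&
            xor(frac < config$open_frac_target, stats::runif(1) < 0.1)
          current <- if (explore_open) sample(open_arms, 1) else sample(closed_arms, 1)
          dwell <- if (current %in% open_arms) rtrunc_exp(8, 1.5, 20) else
            rtrunc_exp(16, 3, 40)
        } else {
          current <- "center"
          dwell <- stats::runif(1, 1, 2.5)
        }
        anchor <- new_anchor(current)
        # dwell counts from arrival: add the travel time to the new anchor
        bout_end <- t_now + dwell + sqrt(sum((anchor - pos)^2)) / 12
      }
      step_to <- anchor - pos
      dist <- sqrt(sum(step_to^2))
      pos <- if (dist > speed) pos + step_to / dist * speed else anchor
      pos <- clamp_footprint(pos + stats::rnorm(2, 0, jitter_sd))
      xs[i] <- pos[1]; ys[i] <- pos[2]
      if (abs(pos[open_ax]) > half && abs(pos[3L - open_ax]) <= half) {
        open_samples <- open_samples + 1L
      }
    }

    track <- tibble::tibble(
      time_s = (seq_len(n_total) - 1) / fs,
      x_cm = xs, y_cm = ys
    )
    # ground-truth centre entries from the rendered track itself
    labels <- classify_zones(track, geometry)
    runs <- zone_runs(labels, min_dwell_s = 0.3)
    is_center <- runs$zone == "center"
    entries <- runs$t_start[is_center & c(FALSE, utils::head(!is_center, -1))]
    list(track = track, events = entries)
  })
}

#' Generate a WT/Het cohort of synthetic sessions
#'
#' Wild-type sessions carry an `approach_gain > 1` coupling ramp at centre
#' entries and full baseline coupling; heterozygote sessions are flat
#' (`approach_gain = 1`) with a global coupling reduction
#' (`het_coupling_scale`, default 0.6) and a higher open-arm occupancy
#' target. Per-session seeds derive deterministically from the base seed.
#'
#' With `heterogeneity = TRUE` (the default), each animal's session draws
#' its own spectral parameters — theta frequency (7.5-8.5 Hz), theta peak
#' height (4-8), 1/f exponent (0.9-1.2) and per-band carrier amplitudes
#' (0.55-1.15) —
#' emulating the across-animal variability (electrode placement, spectra)
#' of real cohorts. Without it, every session shares one generative
#' process and even unrelated per-animal components look alike, which no
#' real cohort does.
#'
#' @param n_wt,n_het Number of sessions per genotype (the in vivo cohort
#'   was 7 WT and 6 Het).
#' @param base A [synth_config()] used as the template.
#' @param seed Cohort seed (overrides `base$seed`).
#' @param het_coupling_scale Baseline coupling multiplier for Het sessions.
#' @param het_open_frac Open-arm occupancy target for Het sessions
#'   (default 0.30 vs the WT template's 0.15).
#' @param heterogeneity Draw per-animal spectral parameters (default
#'   `TRUE`).
#' @param geometry An [epm_geometry()].
#' @return List of session objects, each with `id`, `genotype`,
#'   `recording`, `track`, `truth` and `config`.
#' @export
generate_cohort <- function(n_wt = 7, n_het = 6, base = synth_config(),
                            seed = base$seed, het_coupling_scale = 0.6,
                            het_open_frac = 0.30, heterogeneity = TRUE,
                            geometry = epm_geometry()) {
  stopifnot(n_wt >= 0, n_het >= 0, n_wt + n_het >= 1)
  genos <- c(rep("WT", n_wt), rep("Het", n_het))
  purrr::imap(genos, function(g, idx) {
    cfg <- base
    cfg$seed <- as.integer(seed + 101L * idx)
    if (g == "Het") {
      cfg$approach_gain <- 1
      cfg$coupling_scale <- base$coupling_scale * het_coupling_scale
      cfg$open_frac_target <- het_open_frac
    }
    # the coupling network is a continuously active latent source: slow
    # wander in every animal (its event-locked ramp differs by genotype)
    if (cfg$coupling_wander == 0) cfg$coupling_wander <- 0.25
    if (heterogeneity) {
      withr::with_seed(cfg$seed + 7L, {
        cfg$theta_freq <- stats::runif(1, 7.5, 8.5)
        cfg$theta_snr <- stats::runif(1, 4, 8)
        cfg$noise_exponent <- stats::runif(1, 0.9, 1.2)
        cfg$high_amp <- stats::runif(3, 0.55, 1.15)
      })
    }
    cfg <- do.call(synth_config, unclass(cfg))
    id <- sprintf("%s_%02d", tolower(g), idx)
    beh <- generate_epm_session(cfg, geometry)
    lfp <- generate_lfp_pair(cfg, events = beh$events, id = id, genotype = g)
    list(
      id = id, genotype = g,
      recording = lfp$recording,
      track = beh$track,
      truth = c(lfp$truth, list(track_events = beh$events)),
      config = cfg
    )
  })
}

#' Write / read a tracking table as CSV
#'
#' Plain ANY-maze-like export: columns `time_s`, `x_cm`, `y_cm`.
#'
#' @param track Tracking tibble.
#' @param path File path.
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(track[, c("time_s", "x_cm", "y_cm")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))[, c("time_s", "x_cm", "y_cm")]
}

#' Write / read a generator configuration as YAML
#'
#' @param config A [synth_config()].
#' @param path YAML file path.
#' @export
write_synth_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required", call. = FALSE)
  }
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_synth_config_yaml
#' @export
read_synth_config_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required", call. = FALSE)
  }
  do.call(synth_config, yaml::read_yaml(path))
}
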