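---
title: "Methods: hippocampal-prefrontal theta communication analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hippocampal-prefrontal theta communication analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scientific setting

Theta-frequency (4-12 Hz) synchronization between the ventral hippocampus
(vHPC) and medial prefrontal cortex (mPFC) is a biomarker of the
communication required for normal anxiety-related avoidance in the elevated
plus maze (EPM). As a mouse leaves a closed arm and approaches the centre of
the maze — the decision point between avoiding and exploring the open arms —
vHPC-mPFC theta synchrony transiently rises. `thetacomm` implements the
complete analysis chain for studying this phenomenon from paired LFP
recordings and position tracking: band-limited spectral features, synchrony
and cross-frequency coupling statistics, event-locked dynamics around centre
approaches, data-driven discovery of conserved "coherence networks" across
animals, and a minimal circuit model explaining why feedforward inhibition
onto fast-spiking interneurons (FSINs) is needed to transmit rhythmic
hippocampal input selectively.

Because genuine recordings are not required for validating the machinery,
the package ships a seeded synthetic-data generator whose sessions have
*known* coupling ground truth; every downstream stage is tested against that
ground truth.

## Signal model and feature set

All spectral analysis is Hilbert-based. Signals are zero-phase FIR filtered
(Hamming design; kernel length three periods of the band's lower edge,
`round(3 * fs / lo)` samples, applied forward-backward via the kernel
autocorrelation so no phase distortion is introduced), then the analytic
signal gives instantaneous amplitude and phase. Half a kernel length at each
session edge is discarded before any statistic is computed, because Hilbert
edge transients corrupt instantaneous phase.

The 40-feature catalogue (`feature_catalog()`) combines:

* **Band power** (8): Welch's method with nonoverlapping 2 s segments for
  bulk estimates — 2 s resolves 1 Hz granularity with multiple theta cycles
  per segment — in theta (4-12), beta (13-30), low gamma (30-55) and high
  gamma (65-100 Hz), per region. Within the short 2.5 s dynamic windows the
  band power is computed as the mean squared band-passed signal (the band
  variance), since a 2.5 s window cannot hold more than one nonoverlapping
  2 s Welch segment.
* **Weighted phase-lag index** (4): `WPLI = |mean(Im S)| / mean(|Im S|)`
  with the per-sample cross-term `S = z_hpc * Conj(z_pfc)` from the
  band-limited analytic signals. Using only the imaginary part makes the
  statistic blind to zero-lag (volume-conducted) mixing. The plain
  (non-debiased) ratio is the default; the debiased squared variant is an
  option. When `mean(|Im S|) = 0` (e.g. identical inputs) the statistic is
  defined as 0: no imaginary structure means no measurable lagged synchrony.
  The cross-term order is fixed so a positive mean imaginary part means the
  hippocampus leads (`lead_lag_sign()`).
* **Amplitude covariation** (4): Pearson correlation of the two channels'
  instantaneous band amplitudes.
* **Phase-amplitude coupling** (24): each time point contributes the vector
  `A_high * exp(1i * phi_low)`; the modulus of the vector sum normalized by
  the summed amplitude is the modulation index, in [0, 1]. For an amplitude
  `1 + m cos(phi)` with uniform phase coverage the index converges to `m/2`.
  Low bands are theta (2-6) and alpha (6-10 Hz); high bands beta, low and
  high gamma; all four region combinations of phase source and amplitude
  source are included.

Event-locked ("dynamic") measures are evaluated on 2.5 s windows centred at
11 grid points, 1.5 s apart, from 7.5 s before to 7.5 s after a centre
entry, and z-scored within each run relative to the rest of that run.
Windows are centred on grid points (symmetric spectral leakage around the
event); the same 2.5 s / 1.5 s windowing, advanced continuously, provides
the feature time series for network discovery so that one windowing
convention serves both stages.

## EPM scoring

`classify_zones()` labels samples open / closed / centre from a
plus-shaped geometry (default 30 x 5 cm arms around a 5 x 5 cm centre —
standard mouse dimensions; all configurable). Zone bouts shorter than 0.5 s
are absorbed into the surrounding zone before entries are counted, a
hysteresis against tracking jitter. A *run event* is the first centre sample
after at least 1.5 s in a closed arm (so the pre-event window reflects
closed-arm context); it is a closed-centre-open run if the next non-centre
zone reached is open. The tracked point is taken as given — no
centre-of-mass vs nose-point distinction is attempted.

## Network discovery

Per animal, the z-scored windowed feature matrix is decomposed by PCA; the
number of retained components is the count of correlation-matrix eigenvalues
above the Marchenko-Pastur upper edge `(1 + sqrt(p/n))^2` (unit variance is
appropriate because the features are standardized). FastICA (logcosh
contrast, symmetric extraction, tolerance 1e-4 as in the reference
implementations, at most 1000 iterations, seeded, with up to three seeded
restarts on non-convergence) unmixes the retained components; each
component's weight vector is back-projected to feature space, unit-normed,
and sign-canonicalized (largest-magnitude weight positive).

Components are compared across animals by the correlation of their weight
vectors computed on sign-aligned vectors (equivalently `|r|`), because ICA
signs are arbitrary — without alignment, identical networks with flipped
signs would spuriously fail the similarity threshold. Similarity is a
cross-animal notion: two components of the same animal are distinct
networks by construction, so within-animal pairs contribute no edges
(their non-orthogonal feature-space patterns routinely correlate above any
threshold and would chain unrelated clusters). Pairs with `|r| > 0.7`
define a graph; connected components spanning at least three animals are
conserved networks, and the characteristic IC is the renormalized mean of
sign-aligned members. Connected-component clustering is single-linkage and
therefore chain-prone: components that partially express a strong shared
latent source can pull moderately related components into one cluster, so
a recovered cluster's characteristic should always be inspected against
the loading families it claims. Projecting the characteristic weights onto each
animal's z-scored features (a per-window dot product) gives the network's
activity time course, which can be event-aligned and z-scored like any
feature.

## The feedforward-inhibition model

Two (optionally three) current-based leaky integrate-and-fire cells receive
the same two Poisson inputs: "hippocampal" spikes whose rate varies
sinusoidally between 0 and 100 Hz at 8 Hz (starting at the rate minimum, a
fixed but arbitrary phase), and "noise" spikes at the constant midpoint
rate, 50 Hz. Synaptic drives decay exponentially with 8 ms (excitation) and
20 ms (inhibition) time constants — inhibition outlasting excitation is
what makes feedforward inhibition a temporal filter. The remaining constants
are conventional and configurable: membrane time constant 20 ms, threshold 1
and reset 0 in dimensionless potential units, 2 ms refractory period,
0.1 ms Euler step (the step must satisfy `dt < min(tau_e, tau_m)/5`). Input
spikes are drawn per-bin with probability `rate * dt` (valid only while
`rate * dt < 0.2`; finer steps are enforced otherwise).

`calibrate_operating_point()` finds weights realizing the operating point —
FSIN ~20 Hz, pyramidal ~25 Hz with inhibition and ~50 Hz without — by three
coordinate bisections (excitatory weight onto the pyramidal cell, excitatory
weight onto the FSIN, inhibitory weight magnitude), exploiting the
monotonicity of each rate in the corresponding weight. Candidate weights are
evaluated on a fixed set of input realizations (common random numbers), so
each bisected function is deterministic and monotone.

`sweep_fsin_drive()` scales the two excitatory weights onto the FSIN
together (a single drive parameter; a hippocampal-only mode is also
provided) over 0 to 2x the calibrated drive — the sweep range is defined
relative to the calibrated operating point since no absolute scale is
privileged. At each point it reports mean rates, the Pearson correlation of
10 ms-binned pyramidal output with each input train, and their ratio
(SNR). Correlations are computed per 1 s trial then averaged (the
concatenated-bin alternative exists as an option); 10 ms bins resolve theta
cycles without making counts too sparse. The disinhibition variant adds an
interneuron-selective interneuron that receives the same feedforward
excitation and inhibits the FSIN; with its weights at zero the variant
reduces bit-for-bit to the base circuit. `frequency_sweep()` repeats the
measurement across hippocampal modulation frequencies.

The compiled (Rcpp) integrator is validated spike-for-spike against a
plain-R per-step reference loop with the same update equations at a 0.01 ms
step.

## Statistics

`rank_sum()` implements the two-sided Wilcoxon rank-sum test: exact mode
enumerates all label assignments of the pooled sample (midranks for ties;
two-sided p is twice the smaller tail, capped at 1; limited to combined
n <= 20), and normal mode standardizes with the tie-corrected variance.

The timepoint-by-genotype interaction question — does the event-locked rise
differ between genotypes? — is answered by an animal-level permutation test
rather than a linear mixed model: the run-level contrast is the z-scored
value at t = 0 minus the mean of the first and last grid points (a
near-event-timepoints contrast is available as an option), contrasts are
averaged within animal, and genotype labels are permuted across animals so
each animal's runs stay together. Permuting animals rather than runs
preserves within-animal correlation, which is exactly what the mixed model's
random effect would account for; the package also exports a tidy per-run
table for external mixed-model fitting. With fewer than 100 distinct label
assignments the null is enumerated exactly. Sampled p-values use the
add-one correction, so p is never below `1/(n_perm + 1)`.

## The synthetic generator

`generate_lfp_pair()` builds each channel as (i) unit-variance 1/f
background (spectral shaping of white noise, exponent 1); (ii) a theta
rhythm synthesized as band-limited Gaussian noise in `theta_freq +/-
1.5 Hz` (strictly interior to the 6-10 Hz analysis band, so the
estimator's own filter does not distort the phase it must recover), of
which a fraction `coupling_strength` is shared between channels with the
prefrontal copy rotated by `phase_lag` (positive = hippocampus leads);
(iii) an independent delta/low-theta rhythm (2.5-5.5 Hz) per channel,
giving the low-frequency phase bands genuine, steadily rotating content;
(iv) beta/low-gamma/high-gamma carriers (two summed band-limited noise
components per band in 17-27, 36-48, 74-90 Hz, keeping most theta
amplitude-modulation sidebands inside the measurement bands and smoothing
single-component Rayleigh envelope fluctuations) whose envelopes are
modulated by the shared theta phase with depth `cfc_depth`; and (v) slow
(0.02-0.1 Hz) arousal-like state drifts — independent gains on each
channel's theta amplitude and carrier amplitude — that enrich the
session's factor structure the way real recordings are rich, which also
gives the decomposition stage realistic dimensionality to work with. A band-limited noise process was chosen over a
phase-drifting sinusoid deliberately: it has uniform phase coverage and a
naturally fluctuating Hilbert envelope, and independent draws decohere
within ~1/bandwidth seconds, so independent-channel synchrony nulls behave
correctly — a constant-amplitude oscillator stays spuriously phase-locked
across seconds.

Around each centre entry, coupling and modulation depth ramp linearly from
3 s before the entry to a peak at entry, decaying over 1.5 s — a shape that
gives the pipeline a recoverable event-locked signal. Wild-type sessions
use `approach_gain > 1` (default 2.2, ramping the modulation depth to its
ceiling at entry); heterozygote sessions are flat (`approach_gain = 1`)
and carry a global 0.6 coupling reduction emulating the baseline deficit,
plus a higher open-arm occupancy target (0.30 vs 0.15). A slow coupling
"wander" (band 0.02-0.08 Hz) makes the coupling network a continuously
active latent source; cohorts enable it by default (SD 0.25) because a
latent that is only active during the ~15% of the session covered by
approach ramps is recovered inconsistently by ICA, whereas its
genotype-specific event-locked ramp rides on top either way. With
near-constant coupling, per-window WPLI estimator noise (each 2.5 s window
holds only ~10 independent theta cycles) dominates any session-internal
variation, which is why recoverability is checked on wander sessions with
5 s windows. Cohorts additionally draw per-animal spectral parameters
(theta frequency 7.5-8.5 Hz, theta peak height 4-8, 1/f exponent 0.9-1.2,
per-band carrier amplitudes 0.55-1.15): with every animal sharing one
identical generative process, even unrelated per-animal components look
alike across animals — something no real cohort shows — and the
similarity graph degenerates.

`generate_epm_session()` renders a continuous trajectory at 30 Hz: zone
bouts (exponential dwells, closed ~16 s, open ~8 s, centre 1-2.5 s) with a
feedback controller steering realized open-arm occupancy to the target, and
positions moving along arm centrelines at ~12 cm/s with jitter, clamped to
the plus-shaped footprint so every transition passes through the centre.
Ground-truth centre-entry times are read back from the rendered track
itself.

What the generator does *not* emulate: movement artifacts, volume
conduction, electrode drift, inter-animal spectral heterogeneity, behaviour
beyond zone occupancy, and any spike-level structure. Passing tests
therefore demonstrate that the pipeline recovers planted coupling structure
under realistic spectra and event statistics — not that it is robust to
every pathology of real recordings.

Two estimator-vs-truth caveats are documented rather than hidden. First,
the measured phase-amplitude coupling on generated sessions is proportional
to the programmed depth `m` but attenuated relative to the `m/2` limit
(roughly 0.7x at full coupling) by in-band background amplitude and
phase-estimation noise; the `m/2` closed form is verified on the clean
amplitude-modulation construction that defines the statistic. Second, the
generator's theta (8 Hz) falls in the *alpha* (6-10 Hz) low band of the
cross-frequency catalogue, whose "theta" phase band is 2-6 Hz; planted
network checks therefore target the hippocampal-phase coupling features as
a group, whatever the band label.

## Problem sizes and numerical choices in the test-suite

The validation suite exercises: full 900 s sessions at 2000 Hz for
occupancy and event statistics; 120-600 s sessions for synchrony and
recoverability; a 13-animal cohort (7 WT / 6 Het, full-length sessions) for
the end-to-end network-discovery round trip; 1000 simulated cohorts for the
permutation test's type-I calibration and 200 for power; and reduced
trial counts (150-300 of the 1000 x 1 s iterations used for headline
numbers) for circuit-model shape checks. Degenerate inputs (zero signals,
constant amplitudes, zero-variance runs, empty event lists) return flagged
zeros or errors as documented on each function.

## Known limitations

* Bulk measures are computed over all samples; no artifact/immobility mask
  is applied by default (an optional mask argument would be the natural
  extension).
* The Welch segment length (2 s) and the dynamic-window power estimator are
  choices the source methods leave open; both are stated above and
  configurable.
* The per-animal ICA dimensionality is whatever the Marchenko-Pastur gate
  returns for that session; no cross-animal harmonization of k is applied.
* The circuit model is current-based with a single compartment per cell; no
  conductances, no cell-intrinsic rhythmicity.
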