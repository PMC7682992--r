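Package: thetacomm
Title: Hippocampal-Prefrontal Theta Communication Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing theta-frequency communication between the
    ventral hippocampus and medial prefrontal cortex from paired local field
    potential recordings during elevated-plus-maze behaviour. Implements
    band-limited spectral features (Welch band power, weighted phase-lag
    index, amplitude covariation, theta-phase to beta/gamma-amplitude
    coupling), event-locked feature dynamics around centre approaches,
    data-driven discovery of cross-animal coherence networks by PCA with
    Marchenko-Pastur dimensionality selection, FastICA and graph clustering
    of component weights, scoring of elevated-plus-maze trajectories,
    quantification of optically evoked slice responses, a leaky
    integrate-and-fire model of theta-gated feedforward inhibition, and
    rank-sum plus animal-level permutation statistics. A seeded synthetic-data
    generator produces paired LFP and trajectory cohorts with known coupling
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
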