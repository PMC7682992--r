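#' Frequency band specification
#'
#' A band is a half-open description of a frequency interval used for FIR
#' filtering, band power, synchrony and cross-frequency coupling. The
#' canonical single-frequency bands are theta (4-12 Hz), beta (13-30 Hz),
#' low gamma (30-55 Hz) and high gamma (65-100 Hz); cross-frequency phase
#' bands are a narrower theta (2-6 Hz) and alpha (6-10 Hz).
#'
#' @param name Short label, e.g. `"theta"`.
#' @param lo,hi Band edges in Hz, `0 < lo < hi`.
#' @return A `band_spec` list with elements `name`, `lo`, `hi`.
#' @export
#' @examples
#' band_spec("theta", 4, 12)
band_spec <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || hi <= lo) {
    stop("band edges must satisfy 0 < lo < hi", call. = FALSE)
  }
  structure(list(name = name, lo = lo, hi = hi), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz>\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' Canonical frequency bands
#'
#' `single_freq_bands()` returns the four bands used for power, weighted
#' phase-lag index and amplitude covariation. `cfc_low_bands()` and
#' `cfc_high_bands()` return the phase-source and amplitude-source bands of
#' the cross-frequency coupling features.
#'
#' @return A named list of [band_spec()] objects.
#' @export
single_freq_bands <- function() {
  list(
    theta     = band_spec("theta", 4, 12),
    beta      = band_spec("beta", 13, 30),
    lowGamma  = band_spec("lowGamma", 30, 55),
    highGamma = band_spec("highGamma", 65, 100)
  )
}

#' @rdname single_freq_bands
#' @export
cfc_low_bands <- function() {
  list(
    Theta = band_spec("Theta", 2, 6),
    Alpha = band_spec("Alpha", 6, 10)
  )
}

#' @rdname single_freq_bands
#' @export
cfc_high_bands <- function() {
  list(
    Beta      = band_spec("Beta", 13, 30),
    LowGamma  = band_spec("LowGamma", 30, 55),
    HighGamma = band_spec("HighGamma", 65, 100)
  )
}

#' The 40-feature catalogue
#'
#' Enumerates the full feature set used for network discovery: 8 band powers
#' (2 regions x 4 bands), 4 cross-region amplitude covariations, 4
#' cross-region weighted phase-lag indices, and 24 phase-amplitude coupling
#' features (2 phase regions x 2 low bands x 2 amplitude regions x 3 high
#' bands).
#'
#' @return A tibble with columns `feature`, `kind`, and the defining
#'   region/band fields.
#' @export
#' @examples
#' nrow(feature_catalog())  # 40
feature_catalog <- function() {
  sf <- names(single_freq_bands())
  pow <- tidyr::expand_grid(region = c("hpc", "pfc"), band = sf) |>
    dplyr::mutate(
      kind = "power",
      feature = paste0("pow_", .data$region, "_", .data$band)
    )
  amp <- tibble::tibble(region = "hpcPfc", band = sf) |>
    dplyr::mutate(
      kind = "ampcov",
      feature = paste0("ampcov_hpcPfc_", .data$band)
    )
  wp <- tibble::tibble(region = "hpcPfc", band = sf) |>
    dplyr::mutate(
      kind = "wpli",
      feature = paste0("wpli_hpcPfc_", .data$band)
    )
  cfc <- tidyr::expand_grid(
    phase_region = c("hpc", "pfc"),
    low = names(cfc_low_bands()),
    amp_region = c("hpc", "pfc"),
    high = names(cfc_high_bands())
  ) |>
    dplyr::mutate(
      kind = "cfc",
      feature = paste0(
        "cfc_", .data$phase_region, .data$low, "_",
        .data$amp_region, .data$high
      )
    )
  dplyr::bind_rows(
    dplyr::select(pow, "feature", "kind", "region", "band"),
    dplyr::select(amp, "feature", "kind", "region", "band"),
    dplyr::select(wp, "feature", "kind", "region", "band"),
    dplyr::select(cfc, "feature", "kind", "phase_region", "low",
                  "amp_region", "high")
  )
}
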