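#' Plot an elevated-plus-maze track
#'
#' Occupancy plot of the trajectory coloured by zone, with the maze
#' outline.
#'
#' @param track Tibble `time_s`, `x_cm`, `y_cm`.
#' @param geometry An [epm_geometry()].
#' @return A ggplot object.
#' @export
plot_epm_track <- function(track, geometry = epm_geometry()) {
  labels <- classify_zones(track, geometry)
  ggplot2::ggplot(labels, ggplot2::aes(.data$x_cm, .data$y_cm,
                                       colour = .data$zone)) +
    ggplot2::geom_path(linewidth = 0.2, alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", colour = "zone") +
    ggplot2::theme_minimal()
}

#' Plot a Welch power spectrum
#'
#' @param rec A [paired_recording()].
#' @param fmax Upper frequency limit for display (Hz).
#' @param segment_s Welch segment length (s).
#' @return A ggplot object (log10 power vs frequency, one line per
#'   channel).
#' @export
plot_psd <- function(rec, fmax = 100, segment_s = 2) {
  spec <- dplyr::bind_rows(
    dplyr::mutate(welch_psd(rec$hpc, rec$fs, segment_s), channel = "vHPC"),
    dplyr::mutate(welch_psd(rec$pfc, rec$fs, segment_s), channel = "mPFC")
  ) |>
    dplyr::filter(.data$freq > 0, .data$freq <= fmax)
  ggplot2::ggplot(spec, ggplot2::aes(.data$freq, .data$psd,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "PSD (power/Hz)") +
    ggplot2::theme_minimal()
}

#' Event-locked dynamics plot
#'
#' Mean +/- SEM of z-scored aligned grids by genotype (or a single trace
#' when no genotype column is present).
#'
#' @param aligned Long tibble `run`, `time_rel`, `value`, optionally
#'   `genotype`.
#' @return A ggplot object.
#' @export
plot_event_dynamics <- function(aligned) {
  grp <- if ("genotype" %in% names(aligned)) "genotype" else NULL
  summ <- aligned |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "time_rel")))) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  p <- ggplot2::ggplot(summ, ggplot2::aes(.data$time_rel, .data$mean))
  if (!is.null(grp)) {
    p <- p + ggplot2::aes(colour = .data$genotype, fill = .data$genotype)
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from centre entry (s)", y = "z-score") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ic_cluster_set <- function(object, ...) {
  td <- tidy(object)
  if (!nrow(td)) stop("no clusters to plot", call. = FALSE)
  td$feature <- factor(td$feature, levels = feature_catalog()$feature)
  ggplot2::ggplot(td, ggplot2::aes(.data$feature, .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~cluster, ncol = 1) +
    ggplot2::labs(x = NULL, y = "characteristic IC weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6))
}

#' @export
autoplot.lif_sweep <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(drive = object$drive, panel = "input-output correlation",
                   series = "hippocampal", value = object$corr_hpc),
    tibble::tibble(drive = object$drive, panel = "input-output correlation",
                   series = "noise", value = object$corr_noise),
    tibble::tibble(drive = object$drive, panel = "firing rate (Hz)",
                   series = "pyramidal", value = object$rate_pyr),
    tibble::tibble(drive = object$drive, panel = "firing rate (Hz)",
                   series = "FSIN", value = object$rate_fsin),
    tibble::tibble(drive = object$drive, panel = "SNR (corr ratio)",
                   series = "hpc / noise", value = object$snr)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$drive, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "FSIN excitatory drive (x calibrated)", y = NULL) +
    ggplot2::theme_minimal()
}
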