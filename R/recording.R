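#' Paired two-channel LFP recording
#'
#' Container for synchronized hippocampal and prefrontal voltage series.
#'
#' @param hpc,pfc Numeric vectors of equal length (ventral hippocampal and
#'   medial prefrontal channels).
#' @param fs Sampling rate (samples/s).
#' @param id Session/animal identifier.
#' @param genotype Optional genotype label (e.g. `"WT"`, `"Het"`).
#' @return A `paired_recording` object.
#' @export
paired_recording <- function(hpc, pfc, fs, id = "session", genotype = NA_character_) {
  if (length(hpc) != length(pfc)) stop("channels must have equal length", call. = FALSE)
  if (!all(is.finite(hpc)) || !all(is.finite(pfc))) {
    stop("channels must be finite", call. = FALSE)
  }
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  structure(
    list(hpc = hpc, pfc = pfc, fs = fs, id = id, genotype = genotype),
    class = "paired_recording"
  )
}

#' @export
print.paired_recording <- function(x, ...) {
  cat(sprintf(
    "<paired_recording '%s'%s: %.1f s at %g Hz>\n",
    x$id,
    if (is.na(x$genotype)) "" else paste0(" [", x$genotype, "]"),
    length(x$hpc) / x$fs, x$fs
  ))
  invisible(x)
}

#' Session duration in seconds
#' @param rec A [paired_recording()].
#' @export
duration_s <- function(rec) length(rec$hpc) / rec$fs

#' Write / read a paired recording as plain CSV
#'
#' Columns `time_s`, `hpc`, `pfc`; sampling rate recovered from the time
#' column on read. A thin plain-text interchange format; large sessions are
#' better regenerated from their seed.
#'
#' @param rec A [paired_recording()].
#' @param path File path.
#' @export
write_recording_csv <- function(rec, path) {
  df <- data.frame(
    time_s = (seq_along(rec$hpc) - 1) / rec$fs,
    hpc = rec$hpc, pfc = rec$pfc
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param id,genotype Metadata for the reconstructed object.
#' @export
read_recording_csv <- function(path, id = "session", genotype = NA_character_) {
  df <- utils::read.csv(path)
  fs <- 1 / stats::median(diff(df$time_s))
  paired_recording(df$hpc, df$pfc, fs = round(fs), id = id, genotype = genotype)
}
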