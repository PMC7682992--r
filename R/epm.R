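#' Elevated-plus-maze geometry
#'
#' Four arms crossing at a central square. Two opposite arms are open and
#' two are closed; by default the open arms lie along the x axis. Standard
#' mouse dimensions (30 x 5 cm arms, 5 x 5 cm centre) are the default and
#' all are configurable.
#'
#' @param arm_length_cm,arm_width_cm Arm dimensions (cm).
#' @param center_cm Side of the central square (cm).
#' @param open_axis `"x"` or `"y"`: axis carrying the open arms.
#' @return An `epm_geometry` list.
#' @export
epm_geometry <- function(arm_length_cm = 30, arm_width_cm = 5,
                         center_cm = 5, open_axis = c("x", "y")) {
  open_axis <- match.arg(open_axis)
  stopifnot(arm_length_cm > 0, arm_width_cm > 0, center_cm > 0)
  structure(
    list(
      arm_length_cm = arm_length_cm, arm_width_cm = arm_width_cm,
      center_cm = center_cm, open_axis = open_axis
    ),
    class = "epm_geometry"
  )
}

#' Classify tracking samples into maze zones
#'
#' Labels every sample `open`, `closed` or `center` using the maze
#' geometry, and records which arm (`E`, `W`, `N`, `S`, or `center`) the
#' animal occupies. Samples outside the maze footprint (tracking noise at
#' corners) are snapped to the nearest zone along the dominant axis; the
#' number snapped is reported via the `snapped` attribute.
#'
#' @param track Tibble with columns `time_s`, `x_cm`, `y_cm`.
#' @param geometry An [epm_geometry()].
#' @return `track` with added `zone` and `arm` columns.
#' @export
classify_zones <- function(track, geometry = epm_geometry()) {
  stopifnot(all(c("time_s", "x_cm", "y_cm") %in% names(track)))
  if (!nrow(track)) stop("empty track", call. = FALSE)
  half <- geometry$center_cm / 2
  x <- track$x_cm; y <- track$y_cm
  in_center <- abs(x) <= half & abs(y) <= half
  on_x <- abs(x) > half & abs(y) <= half
  on_y <- abs(y) > half & abs(x) <= half
  outside <- !(in_center | on_x | on_y)
  # snap corner points to the arm of the dominant coordinate
  on_x[outside & abs(x) >= abs(y)] <- TRUE
  on_y[outside & abs(y) > abs(x)] <- TRUE
  arm <- rep("center", length(x))
  arm[on_x] <- ifelse(x[on_x] > 0, "E", "W")
  arm[on_y] <- ifelse(y[on_y] > 0, "N", "S")
  open_arms <- if (geometry$open_axis == "x") c("E", "W") else c("N", "S")
  zone <- ifelse(arm == "center", "center",
                 ifelse(arm %in% open_arms, "open", "closed"))
  out <- dplyr::mutate(tibble::as_tibble(track), zone = zone, arm = arm)
  attr(out, "snapped") <- sum(outside)
  out
}

# Run-length view of the zone sequence with dwell times.
zone_runs <- function(labels, min_dwell_s = 0) {
  r <- rle(labels$zone)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  t <- labels$time_s
  dt <- stats::median(diff(t))
  runs <- tibble::tibble(
    zone = r$values,
    start = starts, end = ends,
    t_start = t[starts],
    dwell = t[ends] - t[starts] + dt,
    arm = labels$arm[starts]
  )
  if (min_dwell_s > 0 && nrow(runs) > 1) {
    # hysteresis: absorb sub-threshold bouts into the preceding zone
    keep <- runs$dwell >= min_dwell_s
    keep[1] <- TRUE
    if (!all(keep)) {
      merged <- labels$zone
      for (i in which(!keep)) {
        merged[runs$start[i]:runs$end[i]] <- merged[runs$start[i] - 1L]
      }
      labels2 <- labels
      labels2$zone <- merged
      return(zone_runs(labels2, 0))
    }
  }
  runs
}

#' Occupancy and locomotion metrics for a labelled track
#'
#' Computes the headline elevated-plus-maze measures: time in open and
#' closed arms and centre, the open/closed time ratio, total path length,
#' the number of open-arm entries (with a minimum-dwell hysteresis against
#' tracking jitter) and the mean duration of open-arm visits.
#'
#' @param labels Output of [classify_zones()].
#' @param min_entry_dwell_s Minimum dwell for a zone bout to count
#'   (default 0.5 s).
#' @return One-row tibble of metrics. If no time was spent in the closed
#'   arms the ratio is `NA` and flagged via the `ratio_undefined`
#'   attribute.
#' @export
occupancy_metrics <- function(labels, min_entry_dwell_s = 0.5) {
  t <- labels$time_s
  dt <- stats::median(diff(t))
  ztime <- function(z) sum(labels$zone == z) * dt
  open_t <- ztime("open"); closed_t <- ztime("closed"); center_t <- ztime("center")
  dist <- sum(sqrt(diff(labels$x_cm)^2 + diff(labels$y_cm)^2))
  runs <- zone_runs(labels, min_entry_dwell_s)
  open_runs <- runs[runs$zone == "open", , drop = FALSE]
  out <- tibble::tibble(
    open_time_s = open_t,
    closed_time_s = closed_t,
    center_time_s = center_t,
    open_closed_ratio = if (closed_t > 0) open_t / closed_t else NA_real_,
    distance_cm = dist,
    open_entries = nrow(open_runs),
    mean_open_visit_s = if (nrow(open_runs)) mean(open_runs$dwell) else NA_real_
  )
  if (closed_t == 0) attr(out, "ratio_undefined") <- TRUE
  out
}

#' Detect centre-approach run events
#'
#' A run event is the first centre sample following at least
#' `min_closed_dwell_s` spent in a closed arm. The event is a
#' `closed_center_open` run if the next non-centre zone reached is an open
#' arm, otherwise a `closed_center` run. These events anchor all
#' event-locked analyses.
#'
#' @param labels Output of [classify_zones()].
#' @param min_closed_dwell_s Minimum closed-arm dwell before the approach
#'   (default 1.5 s).
#' @param min_entry_dwell_s Hysteresis for zone bouts (default 0.5 s).
#' @return Tibble with columns `type`, `t_entry`, `source_arm`,
#'   `dest_zone` (possibly empty).
#' @export
detect_runs <- function(labels, min_closed_dwell_s = 1.5,
                        min_entry_dwell_s = 0.5) {
  runs <- zone_runs(labels, min_entry_dwell_s)
  out <- list()
  for (i in seq_len(nrow(runs))) {
    if (runs$zone[i] != "center" || i == 1L) next
    if (runs$zone[i - 1L] != "closed") next
    if (runs$dwell[i - 1L] < min_closed_dwell_s) next
    nxt <- NA_character_
    for (j in seq_len(nrow(runs) - i)) {
      if (runs$zone[i + j] != "center") { nxt <- runs$zone[i + j]; break }
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      type = if (identical(nxt, "open")) "closed_center_open" else "closed_center",
      t_entry = runs$t_start[i],
      source_arm = runs$arm[i - 1L],
      dest_zone = nxt
    )
  }
  if (!length(out)) {
    return(tibble::tibble(
      type = character(), t_entry = numeric(),
      source_arm = character(), dest_zone = character()
    ))
  }
  dplyr::bind_rows(out)
}

#' Align session features to run events
#'
#' Evaluates the event-locked 11-point grids of the requested features at
#' each run's centre-entry time and z-scores each run's grid relative to
#' the rest of that run. Runs too close to the session edges are dropped
#' with a warning.
#'
#' @param rec A [paired_recording()].
#' @param runs Tibble from [detect_runs()] (or any tibble with `t_entry`).
#' @param spec A [dynamic_window_spec()].
#' @param features Character vector of feature names (default: all 40).
#' @return Long tibble `run`, `time_rel`, `feature`, `value` (z-scored
#'   within run and feature).
#' @export
align_to_events <- function(rec, runs, spec = dynamic_window_spec(),
                            features = NULL) {
  if (!nrow(runs)) stop("no usable runs", call. = FALSE)
  grids <- windowed_features(rec, runs$t_entry, spec)
  keep <- c("run", "time_rel", features %||% feature_catalog()$feature)
  grids[, keep] |>
    tidyr::pivot_longer(-c("run", "time_rel"),
                        names_to = "feature", values_to = "value") |>
    dplyr::group_by(.data$run, .data$feature) |>
    dplyr::mutate(value = as.numeric(zscore_run(.data$value))) |>
    dplyr::ungroup()
}

#' Align an arbitrary windowed time course to events
#'
#' Linearly interpolates a time course defined on window centres (e.g. a
#' projected network-activity trace) onto the event-locked grid and
#' z-scores each run.
#'
#' @param time,value The time course (window-centre seconds, values).
#' @param events Event times (s).
#' @param spec A [dynamic_window_spec()].
#' @return Long tibble `run`, `time_rel`, `value` (z-scored per run).
#' @export
align_time_course <- function(time, value, events, spec = dynamic_window_spec()) {
  ok <- events + min(spec$offsets) >= min(time) &
    events + max(spec$offsets) <= max(time)
  if (!all(ok)) {
    warning(sprintf("%d event(s) outside time-course range dropped", sum(!ok)),
            call. = FALSE)
  }
  events <- events[ok]
  if (!length(events)) stop("no usable runs", call. = FALSE)
  grid <- tidyr::expand_grid(run = seq_along(events), time_rel = spec$offsets) |>
    dplyr::mutate(value = stats::approx(time, value,
                                        xout = events[.data$run] + .data$time_rel)$y)
  zscore_event_dynamics(grid)
}
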