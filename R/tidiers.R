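#' Tidy a rank-sum test
#'
#' @param x A `rank_sum_test`.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `p_value`, `mode`, `n1`, `n2`.
#' @export
tidy.rank_sum_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 mode = x$mode, n1 = x$n1, n2 = x$n2)
}

#' Tidy an animal-level permutation test
#'
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return One-row tibble with the observed statistic and p-value.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(observed = x$observed, p_value = x$p_value,
                 n_perm = x$n_perm, exact = x$exact, contrast = x$contrast)
}

#' @rdname tidy.perm_test
#' @export
glance.perm_test <- function(x, ...) tidy(x)

#' Tidy a circuit calibration
#'
#' @param x A `lif_calibration`.
#' @param ... Unused.
#' @return Tibble with one row per calibrated rate: `quantity`, `target`,
#'   `achieved`.
#' @export
tidy.lif_calibration <- function(x, ...) {
  if (is.null(x$achieved)) {
    return(tibble::tibble(quantity = character(), target = numeric(),
                          achieved = numeric()))
  }
  tibble::tibble(
    quantity = names(x$achieved),
    target = as.numeric(x$targets[names(x$achieved)]),
    achieved = as.numeric(x$achieved)
  )
}

#' @rdname tidy.lif_calibration
#' @return `glance()`: one-row tibble with feasibility and the fitted
#'   weights.
#' @export
glance.lif_calibration <- function(x, ...) {
  tibble::tibble(
    feasible = x$feasible,
    w_exc_pyr = if (is.null(x$params)) NA_real_ else x$params$w_hpc_pyr,
    w_exc_fsin = if (is.null(x$params)) NA_real_ else x$params$w_hpc_fsin,
    w_fsin_pyr = if (is.null(x$params)) NA_real_ else x$params$w_fsin_pyr
  )
}

#' Tidy an IC cluster set
#'
#' @param x An `ic_cluster_set`.
#' @param ... Unused.
#' @return Long tibble: `cluster`, `feature`, `weight` (characteristic
#'   weights per cluster).
#' @export
tidy.ic_cluster_set <- function(x, ...) {
  if (!length(x)) {
    return(tibble::tibble(cluster = integer(), feature = character(),
                          weight = numeric()))
  }
  purrr::imap(x, function(cl, i) {
    tibble::tibble(cluster = i, feature = names(cl$weights),
                   weight = as.numeric(cl$weights))
  }) |> dplyr::bind_rows()
}

#' @rdname tidy.ic_cluster_set
#' @return `glance()`: one row per cluster with sizes.
#' @export
glance.ic_cluster_set <- function(x, ...) {
  tibble::tibble(
    cluster = seq_along(x),
    n_members = vapply(x, function(cl) nrow(cl$members), integer(1)),
    n_animals = vapply(x, function(cl) length(cl$animals), integer(1))
  )
}
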