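#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two samples. In `exact` mode the null
#' distribution of the rank sum is built by enumerating every assignment
#' of the pooled values to the two groups and the two-sided p-value is
#' `2 * min(tail probabilities)`, capped at 1 (ties handled by ranking the
#' pooled sample with midranks). In `normal` mode the standardized
#' statistic uses the tie-corrected variance. If every pooled value is
#' identical, p = 1.
#'
#' @param a,b Numeric samples (nonempty).
#' @param mode `"exact"` (combined n <= 20) or `"normal"`.
#' @return A `rank_sum_test` list: `statistic` (z for normal mode, rank
#'   sum of `a` for exact mode), `p_value`, `mode`, sample sizes.
#' @export
#' @examples
#' rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
rank_sum <- function(a, b, mode = c("exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) stop("samples must be nonempty", call. = FALSE)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  if (length(unique(pooled)) == 1L) {
    return(structure(list(statistic = W, p_value = 1, mode = mode,
                          n1 = n1, n2 = n2), class = "rank_sum_test"))
  }
  if (mode == "exact") {
    if (n > 20) stop("exact mode limited to combined n <= 20", call. = FALSE)
    sums <- combn_rank_sums(r, n1)
    lo <- mean(sums <= W); hi <- mean(sums >= W)
    p <- min(1, 2 * min(lo, hi))
    stat <- W
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    stat <- (W - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(stat)))
  }
  structure(list(statistic = stat, p_value = p, mode = mode, n1 = n1, n2 = n2),
            class = "rank_sum_test")
}

combn_rank_sums <- function(r, n1) {
  utils::combn(r, n1, FUN = sum)
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): statistic = %.4g, p = %.4g (n = %d, %d)\n",
              x$mode, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Animal-level permutation test for a timepoint-by-genotype interaction
#'
#' Tests whether the event-locked rise at the centre entry differs between
#' genotypes. Each run contributes an 11-point z-scored grid; the run-level
#' contrast is the value at t = 0 minus a baseline (by default the mean of
#' the first and last grid points; `contrast = "timepoints"` instead
#' averages a set of near-event timepoints against that baseline). The
#' observed statistic is the difference between genotypes of the
#' animal-mean contrast, and the null is built by permuting genotype
#' labels across animals, keeping each animal's runs together — this
#' preserves within-animal correlation, which a run-level shuffle would
#' destroy. When fewer than 100 distinct label assignments exist, all of
#' them are enumerated instead of sampled.
#'
#' @param runs Long tibble with columns `run` (needs only be unique within
#'   its animal), `animal`, `genotype` (two levels), `time_rel`, `value`.
#' @param t0 Grid time treated as the event (default 0).
#' @param timepoints Optional timepoints averaged for the
#'   `"timepoints"` contrast (default `c(-3, -1.5, 0, 1.5)`).
#' @param contrast `"t0_vs_baseline"` (default) or `"timepoints"`.
#' @param n_perm Number of label permutations (default 2000).
#' @param seed Integer seed.
#' @return A `perm_test` list: `p_value`, `observed`, `null` (permuted
#'   statistics), `n_perm`, `exact` (whether enumeration was used).
#' @export
interaction_permutation_test <- function(runs, t0 = 0,
                                         timepoints = c(-3, -1.5, 0, 1.5),
                                         contrast = c("t0_vs_baseline",
                                                      "timepoints"),
                                         n_perm = 2000, seed = 1L) {
  contrast <- match.arg(contrast)
  needed <- c("run", "animal", "genotype", "time_rel", "value")
  stopifnot(all(needed %in% names(runs)))
  genos <- sort(unique(runs$genotype))
  if (length(genos) != 2) stop("need exactly two genotypes", call. = FALSE)

  tmin <- min(runs$time_rel); tmax <- max(runs$time_rel)
  # run ids may be numbered within animal; key them by animal
  runs$run <- paste(runs$animal, runs$run, sep = "\r")
  base_sel <- runs$time_rel %in% c(tmin, tmax)
  peak_sel <- if (contrast == "t0_vs_baseline") {
    runs$time_rel == t0
  } else {
    runs$time_rel %in% timepoints
  }
  peak <- tapply(runs$value[peak_sel], runs$run[peak_sel], mean)
  base <- tapply(runs$value[base_sel], runs$run[base_sel], mean)
  stopifnot(identical(names(peak), names(base)))
  run_animal <- tapply(runs$animal, runs$run, function(x) x[1])[names(peak)]
  run_contrast <- peak - base
  animal_geno <- tapply(runs$genotype, runs$animal, function(x) x[1])
  per_animal <- tibble::tibble(
    animal = names(animal_geno),
    genotype = as.character(animal_geno),
    contrast = as.numeric(tapply(run_contrast, run_animal,
                                 mean)[names(animal_geno)])
  )
  if (min(table(per_animal$genotype)) < 2) {
    stop("need at least 2 animals per genotype", call. = FALSE)
  }

  vals <- per_animal$contrast
  n_a <- nrow(per_animal)
  n_g1 <- sum(per_animal$genotype == genos[1])
  stat_for <- function(is_g1) mean(vals[is_g1]) - mean(vals[!is_g1])
  observed <- stat_for(per_animal$genotype == genos[1])

  n_distinct <- choose(n_a, n_g1)
  if (n_distinct < 100) {
    idx <- utils::combn(n_a, n_g1)
    null <- apply(idx, 2, function(j) stat_for(seq_len(n_a) %in% j))
    p <- mean(abs(null) >= abs(observed) - 1e-12)
    exact <- TRUE
  } else {
    null <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_perm), function(i) {
        stat_for(seq_len(n_a) %in% sample.int(n_a, n_g1))
      }, numeric(1))
    })
    p <- (1 + sum(abs(null) >= abs(observed) - 1e-12)) / (n_perm + 1)
    exact <- FALSE
  }
  structure(
    list(p_value = p, observed = observed, null = null,
         n_perm = if (exact) ncol(idx) else n_perm, exact = exact,
         genotypes = genos, per_animal = per_animal, contrast = contrast),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "Animal-level permutation test (%s): observed = %.3f (%s - %s), p = %.4g (%s%d permutations)\n",
    x$contrast, x$observed, x$genotypes[1], x$genotypes[2], x$p_value,
    if (x$exact) "exact, " else "", x$n_perm))
  invisible(x)
}

#' Export a tidy per-run table for external mixed-model fitting
#'
#' One row per run and timepoint, suitable for linear mixed-effects
#' modelling in external tools.
#'
#' @param runs Long tibble as in [interaction_permutation_test()].
#' @param path CSV path.
#' @export
write_runs_csv <- function(runs, path) {
  cols <- c("run", "animal", "genotype", "time_rel", "value")
  utils::write.csv(runs[, cols], path, row.names = FALSE)
  invisible(path)
}
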