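#' Assemble a z-scored feature matrix for network discovery
#'
#' Takes a windowed feature table (one row per time window, one column per
#' feature, e.g. from [session_features()]), drops constant columns with a
#' warning, and z-scores every remaining column (mean 0, SD 1) — the input
#' convention for the PCA/ICA decomposition stage.
#'
#' @param features Tibble with a `time` column plus feature columns.
#' @param animal Animal/session identifier carried through the pipeline.
#' @return A `feature_matrix` object: list with `X` (windows x features),
#'   `features`, `animal`, `time`, `dropped`.
#' @export
build_feature_matrix <- function(features, animal = "animal") {
  stopifnot("time" %in% names(features))
  X <- as.matrix(features[, setdiff(names(features), "time")])
  if (anyNA(X)) {
    bad <- rowSums(is.na(X)) > 0
    warning(sprintf("%d window(s) with undefined values dropped", sum(bad)),
            call. = FALSE)
    X <- X[!bad, , drop = FALSE]
  }
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("constant feature column(s) dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
  }
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  structure(
    list(X = X, features = colnames(X), animal = animal,
         time = features$time[seq_len(nrow(X))], dropped = dropped),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix '%s': %d windows x %d features>\n",
              x$animal, nrow(x$X), length(x$features)))
  invisible(x)
}

#' Number of significant components by the Marchenko-Pastur bound
#'
#' Counts eigenvalues of the feature correlation matrix exceeding the
#' Marchenko-Pastur upper edge `(1 + sqrt(p/n))^2` — the largest eigenvalue
#' expected from an n x p matrix of independent standard normals (unit
#' variance, appropriate for z-scored features). This sets the
#' dimensionality passed to the ICA.
#'
#' @param fm A [build_feature_matrix()] object (or plain numeric matrix of
#'   z-scored columns).
#' @return Integer count of supra-threshold eigenvalues.
#' @export
count_significant_components <- function(fm) {
  X <- if (inherits(fm, "feature_matrix")) fm$X else as.matrix(fm)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 windows", call. = FALSE)
  if (n <= p) {
    warning("fewer windows than features; Marchenko-Pastur bound unreliable",
            call. = FALSE)
  }
  lambda <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  sum(lambda > (1 + sqrt(p / n))^2)
}

# unit norm + canonical sign (largest-magnitude entry positive)
canonicalize_weights <- function(w) {
  w <- w / sqrt(sum(w^2))
  if (w[which.max(abs(w))] < 0) w <- -w
  w
}

# Symmetric fixed-point FastICA with the logcosh contrast on pre-whitened
# data Z (n x k, identity covariance). Returns the k x k unmixing matrix.
fastica_symmetric <- function(Z, k, max_iter = 1000, tol = 1e-4) {
  n <- nrow(Z)
  W <- matrix(stats::rnorm(k * k), k, k)
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  delta <- Inf
  for (it in seq_len(max_iter)) {
    U <- Z %*% t(W)                 # n x k source estimates
    G <- tanh(U)
    W1 <- crossprod(G, Z) / n - diag(colMeans(1 - G^2), k) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) return(list(W = W, converged = TRUE, iter = it,
                                 delta = delta))
  }
  list(W = W, converged = FALSE, iter = max_iter, delta = delta)
}

#' Independent components of a feature matrix
#'
#' PCA reduces the z-scored feature matrix to `k` components (the
#' Marchenko-Pastur count from [count_significant_components()]), then the
#' FastICA fixed-point algorithm (logcosh contrast, symmetric extraction,
#' tolerance 1e-4 as in the reference implementations, at most 1000
#' iterations) unmixes them into independent
#' sources. Each component's weight vector is its expression in the
#' original feature space (the mixing pattern, back-projected through the
#' PCA), scaled to unit norm and sign-canonicalized (largest-magnitude
#' weight positive) — how strongly each feature moves when the component's
#' activity moves, the quantity compared across animals and projected onto
#' z-scored features. Non-convergence triggers up to
#' three seeded restarts; if none converges (typical when retained
#' components are nearly Gaussian, so the unmixing rotation is
#' ill-determined), the best iterate is returned with a warning and
#' `converged = FALSE`, as in the reference implementations.
#'
#' @param fm A [build_feature_matrix()] object.
#' @param k Number of components (`1 <= k <= p`).
#' @param seed Integer seed for the random unmixing initialization.
#' @param max_iter,tol FastICA iteration controls.
#' @return An `ic_set`: list with `weights` (k x p, unit rows), `sources`
#'   (windows x k activity time courses), `animal`, `features`.
#' @export
run_ica <- function(fm, k, seed = 1L, max_iter = 1000, tol = 1e-4) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$X
  n <- nrow(X); p <- ncol(X)
  if (k < 1 || k > p) stop("k must lie in [1, p]", call. = FALSE)
  sv <- svd(X, nu = 0, nv = k)
  V <- sv$v[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  proj <- V %*% diag(sqrt(n) / d, k)   # feature -> whitened-PC map
  pattern <- V %*% diag(d / sqrt(n), k) # PC -> feature expression map
  Z <- X %*% proj
  if (k == 1) {
    W <- diag(1)
    fit <- list(converged = TRUE, iter = 0L)
  } else {
    # run all seeded restarts; among converged solutions keep the one with
    # the highest logcosh negentropy proxy (deepest contrast optimum)
    negent <- function(W) {
      g <- colMeans(log(cosh(Z %*% t(W))))
      sum((g - 0.3746)^2)           # E[log cosh] of a standard normal
    }
    fit <- NULL
    for (attempt in 0:2) {
      this <- withr::with_seed(as.integer(seed) + 1000L * attempt,
                               fastica_symmetric(Z, k, max_iter, tol))
      this$J <- if (this$converged) negent(this$W) else -Inf
      better <- is.null(fit) ||
        (this$converged && (!fit$converged || this$J > fit$J)) ||
        (!this$converged && !fit$converged && this$delta < fit$delta)
      if (better) fit <- this
    }
    if (!fit$converged) {
      warning(sprintf(
        paste("FastICA did not converge (k = %d, best delta %.2e after %d",
              "iterations x 3 restarts); returning the best iterate"),
        k, fit$delta, max_iter), call. = FALSE)
    }
    W <- fit$W
  }
  weights <- matrix(NA_real_, k, p, dimnames = list(NULL, fm$features))
  for (i in seq_len(k)) {
    weights[i, ] <- canonicalize_weights(pattern %*% W[i, ])
  }
  sources <- Z %*% t(W)
  structure(
    list(weights = weights, sources = sources, animal = fm$animal,
         features = fm$features, k = k, converged = fit$converged),
    class = "ic_set"
  )
}

#' @export
print.ic_set <- function(x, ...) {
  cat(sprintf("<ic_set '%s': %d components over %d features>\n",
              x$animal, x$k, length(x$features)))
  invisible(x)
}

#' Cluster independent components across animals
#'
#' Builds the pairwise correlation matrix between all component weight
#' vectors (sign-aligned, i.e. on `|r|`, because ICA signs are arbitrary),
#' binarizes it at `r_threshold`, takes connected components of the
#' resulting graph, and keeps components whose members span at least
#' `min_animals` distinct animals. Similarity is a cross-animal notion:
#' edges between two components of the same animal are excluded, so two
#' distinct networks within one animal cannot chain clusters together. Each surviving cluster's characteristic
#' weight vector is the renormalized mean of its sign-aligned members.
#'
#' @param ic_sets List of `ic_set` objects (one per animal).
#' @param r_threshold Correlation threshold (default 0.7).
#' @param min_animals Minimum distinct animals per cluster (default 3).
#' @return An `ic_cluster_set`: list of clusters, each with `members`
#'   (tibble `animal`, `component`), `animals`, `weights` (characteristic,
#'   unit norm), `member_weights`.
#' @export
cluster_ics <- function(ic_sets, r_threshold = 0.7, min_animals = 3) {
  stopifnot(length(ic_sets) >= 1)
  W <- do.call(rbind, lapply(ic_sets, function(s) s$weights))
  animal <- unlist(lapply(ic_sets, function(s) rep(s$animal, s$k)))
  comp <- unlist(lapply(ic_sets, function(s) seq_len(s$k)))
  m <- nrow(W)
  R <- abs(stats::cor(t(W)))
  adj <- R > r_threshold
  diag(adj) <- FALSE
  # similarity is defined across animals: two components of the same
  # animal are distinct networks by construction and never share an edge
  adj[outer(animal, animal, "==")] <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  membership <- igraph::components(g)$membership
  clusters <- list()
  for (cid in unique(membership)) {
    idx <- which(membership == cid)
    if (length(idx) < 2) next
    if (length(unique(animal[idx])) < min_animals) next
    ref <- idx[which.max(colSums(R[idx, idx, drop = FALSE]))]
    signs <- sign(W[idx, , drop = FALSE] %*% W[ref, ])
    signs[signs == 0] <- 1
    aligned <- W[idx, , drop = FALSE] * as.vector(signs)
    clusters[[length(clusters) + 1L]] <- list(
      members = tibble::tibble(animal = animal[idx], component = comp[idx]),
      animals = unique(animal[idx]),
      weights = canonicalize_weights(colMeans(aligned)),
      member_weights = aligned
    )
  }
  structure(clusters, class = "ic_cluster_set",
            features = colnames(W), r_threshold = r_threshold,
            min_animals = min_animals, n_ics = m)
}

#' @export
print.ic_cluster_set <- function(x, ...) {
  cat(sprintf("<ic_cluster_set: %d cluster(s) from %d ICs>\n",
              length(x), attr(x, "n_ics")))
  for (i in seq_along(x)) {
    cat(sprintf("  cluster %d: %d ICs from %d animals\n",
                i, nrow(x[[i]]$members), length(x[[i]]$animals)))
  }
  invisible(x)
}

#' Project a characteristic IC onto windowed features
#'
#' The activity time course of a network: per-window dot product of the
#' z-scored feature vector with the characteristic weight vector.
#'
#' @param weights Named numeric weight vector (or a cluster from
#'   [cluster_ics()]).
#' @param fm A [build_feature_matrix()] object (z-scored rows).
#' @return Tibble with `time` and `activity`.
#' @export
project_ic <- function(weights, fm) {
  if (is.list(weights) && !is.null(weights$weights)) weights <- weights$weights
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(names(weights))) {
    if (length(weights) != length(fm$features)) {
      stop("weight/feature dimension mismatch", call. = FALSE)
    }
  } else {
    if (!all(fm$features %in% names(weights))) {
      stop("weight vector missing features present in the matrix", call. = FALSE)
    }
    weights <- weights[fm$features]
  }
  tibble::tibble(time = fm$time, activity = as.vector(fm$X %*% weights))
}
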