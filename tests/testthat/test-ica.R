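feat_names <- feature_catalog()$feature

as_features <- function(X) {
  colnames(X) <- feat_names[seq_len(ncol(X))]
  dplyr::bind_cols(tibble::tibble(time = seq_len(nrow(X))),
                   tibble::as_tibble(X))
}

test_that("the catalogue enumerates 16 single-frequency and 24 cross-frequency features", {
  cat40 <- feature_catalog()
  expect_identical(nrow(cat40), 40L)
  expect_identical(sum(cat40$kind == "cfc"), 24L)
  expect_identical(sum(cat40$kind != "cfc"), 16L)
  expect_false(anyDuplicated(cat40$feature) > 0)
})

test_that("feature matrices are z-scored and constant columns are dropped", {
  set.seed(1)
  X <- matrix(rnorm(500 * 40), 500, 40)
  fm <- build_feature_matrix(as_features(X))
  expect_identical(ncol(fm$X), 40L)
  expect_true(all(abs(colMeans(fm$X)) < 1e-12))
  expect_true(all(abs(apply(fm$X, 2, sd) - 1) < 1e-12))

  X2 <- X; X2[, 5] <- 3
  expect_warning(fm2 <- build_feature_matrix(as_features(X2)), "constant")
  expect_identical(ncol(fm2$X), 39L)
  expect_identical(fm2$dropped, feat_names[5])
})

test_that("Marchenko-Pastur gate separates noise from planted factors", {
  set.seed(2)
  ks <- vapply(1:10, function(i) {
    count_significant_components(matrix(rnorm(4000 * 40), 4000, 40))
  }, numeric(1))
  expect_gte(mean(ks == 0), 0.9)

  f1 <- rnorm(4000)
  X1 <- matrix(rnorm(4000 * 40), 4000, 40) + outer(f1, rep(0.35, 40))
  expect_identical(count_significant_components(scale(X1)), 1L)

  f2 <- rnorm(4000)
  L1 <- c(rep(0.45, 20), rep(0, 20)); L2 <- c(rep(0, 20), rep(0.45, 20))
  X2 <- matrix(rnorm(4000 * 40), 4000, 40) + outer(f1, L1) + outer(f2, L2)
  expect_identical(count_significant_components(scale(X2)), 2L)

  # invariant to column permutation
  perm <- sample(40)
  expect_identical(count_significant_components(scale(X2)[, perm]),
                   count_significant_components(scale(X2)))
  expect_error(count_significant_components(matrix(rnorm(40), 1, 40)), "2")
  expect_warning(count_significant_components(matrix(rnorm(30 * 40), 30, 40)),
                 "fewer windows")
})

test_that("FastICA recovers planted heavy-tailed sources and rank-1 loadings", {
  set.seed(3)
  n <- 4000
  s1 <- rexp(n) * sign(rnorm(n)); s2 <- rexp(n) * sign(rnorm(n))
  A <- matrix(rnorm(80), 40, 2)
  X <- tcrossprod(cbind(s1, s2), A) + 0.1 * matrix(rnorm(n * 40), n, 40)
  fm <- build_feature_matrix(as_features(X))
  ic <- run_ica(fm, 2, seed = 5)
  cc <- abs(stats::cor(ic$sources, cbind(s1, s2)))
  expect_gt(max(cc[, 1]), 0.95)
  expect_gt(max(cc[, 2]), 0.95)
  expect_true(all(abs(sqrt(rowSums(ic$weights^2)) - 1) < 1e-9))
  # canonical sign: largest-magnitude weight positive
  expect_true(all(apply(ic$weights, 1, function(w) w[which.max(abs(w))] > 0)))

  # rank-1 factor: the k = 1 IC matches the top eigenvector of the exact
  # population correlation matrix (closed-form oracle)
  load <- thetacomm:::canonicalize_weights(rnorm(40))
  sigma <- 0.05
  X1 <- outer(rnorm(n), load) + sigma * matrix(rnorm(n * 40), n, 40)
  R_pop <- diag(1 / sqrt(load^2 + sigma^2)) %*%
    (tcrossprod(load) + sigma^2 * diag(40)) %*%
    diag(1 / sqrt(load^2 + sigma^2))
  v_pop <- thetacomm:::canonicalize_weights(eigen(R_pop, symmetric = TRUE)$vectors[, 1])
  fm1 <- build_feature_matrix(as_features(X1))
  ic1 <- run_ica(fm1, 1, seed = 5)
  expect_gt(abs(sum(ic1$weights[1, ] * v_pop)), 0.99)

  # seeded determinism
  ic_b <- run_ica(fm, 2, seed = 5)
  expect_identical(ic$weights, ic_b$weights)
  expect_error(run_ica(fm, 0, seed = 1), "k")
})

test_that("IC clustering requires three animals and survives sign flips and reordering", {
  set.seed(6)
  plant <- thetacomm:::canonicalize_weights(rnorm(40))
  mk_set <- function(animal, ws) {
    W <- t(apply(ws, 1, thetacomm:::canonicalize_weights))
    colnames(W) <- feat_names
    structure(list(weights = W, sources = NULL, animal = animal,
                   features = feat_names, k = nrow(W)),
              class = "ic_set")
  }
  noise_ic <- function() rnorm(40)
  s1 <- mk_set("a", rbind(plant + rnorm(40, 0, 0.02), noise_ic()))
  s2 <- mk_set("b", rbind(-(plant + rnorm(40, 0, 0.02)), noise_ic()))
  s3 <- mk_set("c", rbind(noise_ic(), plant + rnorm(40, 0, 0.02)))
  s4 <- mk_set("d", rbind(noise_ic()))

  cl <- cluster_ics(list(s1, s2, s3, s4))
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$animals, c("a", "b", "c"))
  expect_gt(abs(sum(cl[[1]]$weights * plant)), 0.99)

  # membership invariant to the order animals are supplied in
  cl_r <- cluster_ics(list(s3, s4, s1, s2))
  expect_length(cl_r, 1)
  expect_setequal(cl_r[[1]]$animals, c("a", "b", "c"))
  expect_equal(abs(sum(cl_r[[1]]$weights * cl[[1]]$weights)), 1,
               tolerance = 1e-9)

  # the same plant in only two animals is not a conserved network
  expect_length(cluster_ics(list(s1, s2, s4)), 0)
})

test_that("IC projection is the per-window dot product (identity, nullity, linearity)", {
  set.seed(7)
  X <- matrix(rnorm(200 * 40), 200, 40)
  fm <- build_feature_matrix(as_features(X))
  one_hot <- numeric(40); one_hot[7] <- 1
  names(one_hot) <- fm$features
  expect_equal(project_ic(one_hot, fm)$activity, fm$X[, 7], tolerance = 1e-12)

  row1 <- fm$X[1, ]
  w_orth <- rnorm(40); w_orth <- w_orth - sum(w_orth * row1) / sum(row1^2) * row1
  names(w_orth) <- fm$features
  expect_lt(abs(project_ic(w_orth, fm)$activity[1]), 1e-10)

  w1 <- rnorm(40); w2 <- rnorm(40)
  names(w1) <- names(w2) <- fm$features
  lhs <- project_ic(2 * w1 + 3 * w2, fm)$activity
  rhs <- 2 * project_ic(w1, fm)$activity + 3 * project_ic(w2, fm)$activity
  expect_equal(lhs, rhs, tolerance = 1e-10)

  expect_error(project_ic(rnorm(39), fm), "mismatch")
})
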