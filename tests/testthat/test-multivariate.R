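test_that("mean normalization divides by the feature mean", {
  m <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  nt <- normalize_mean(m)
  expect_equal(unname(nt$values[, "a"]), c(0.5, 1, 1.5))
  expect_equal(unname(nt$values[, "b"]), c(1, 1, 1))
  expect_equal(unname(colMeans(nt$values)), c(1, 1))
  again <- normalize_mean(nt)
  expect_equal(again$values, nt$values)
  expect_error(normalize_mean(cbind(a = c(0, 0))), "a")
})

test_that("z-score normalization standardizes each feature", {
  m <- cbind(a = c(1, 2, 3))
  nt <- normalize_zscore(m)
  expect_equal(unname(nt$values[, "a"]), c(-1, 0, 1) * sqrt(1.5),
               tolerance = 1e-10)
  set.seed(1)
  m2 <- matrix(rlnorm(200, 10, 1), 20, 10,
               dimnames = list(NULL, sprintf("F%02d", 1:10)))
  nt2 <- normalize_zscore(m2)
  expect_lt(max(abs(colMeans(nt2$values))), 1e-9)
  pop_sd <- sqrt(colMeans(sweep(nt2$values, 2, colMeans(nt2$values))^2))
  expect_lt(max(abs(pop_sd - 1)), 1e-9)
  # z-score of a z-scored table is itself
  expect_lt(max(abs(normalize_zscore(nt2)$values - nt2$values)), 1e-9)
  expect_error(normalize_zscore(cbind(c1 = rep(3, 5))), "c1")
  # sample-denominator option
  nt3 <- normalize_zscore(m2, denominator = "sample")
  expect_equal(unname(apply(nt3$values, 2, sd)), rep(1, 10), tolerance = 1e-9)
})

test_that("stored statistics transform held-out data without re-estimation", {
  set.seed(2)
  train <- matrix(rlnorm(100), 10, 10, dimnames = list(NULL, sprintf("F%02d", 1:10)))
  test <- matrix(rlnorm(50), 5, 10, dimnames = list(NULL, sprintf("F%02d", 1:10)))
  nt <- normalize_zscore(train)
  out <- apply_normalization(nt, test)
  expect_equal(out, sweep(sweep(test, 2, nt$center), 2, nt$scale, "/"))
  expect_error(apply_normalization(nt, test[, 1:5]), "lacks")
})

test_that("PCA matches the covariance eigendecomposition oracle", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(24), 6, 4)
    p <- fit_pca(X, n_components = 3)
    o <- prcomp(X, center = TRUE, scale. = FALSE)
    expect_equal(p$eigenvalues, (o$sdev^2)[1:3], tolerance = 1e-8)
    for (j in 1:3)
      expect_equal(abs(sum(p$loadings[, j] * o$rotation[, j])), 1,
                   tolerance = 1e-8)
    # definitional: scores are centered data times loadings
    Xc <- sweep(X, 2, colMeans(X))
    expect_equal(p$scores, Xc %*% p$loadings, tolerance = 1e-10)
    expect_lt(max(abs(crossprod(p$loadings) - diag(3))), 1e-8)
  }
  # rank-1 data put all variance on PC1
  X1 <- cbind(1:10, 1:10)
  expect_equal(fit_pca(X1, 1)$explained_variance_ratio, 1)
  expect_error(fit_pca(X1, 5), "n_components")
})

test_that("PCA of isotropic data splits variance evenly", {
  set.seed(3)
  X <- matrix(rnorm(20000), 10000, 2)
  p <- fit_pca(X, 2)
  expect_equal(unname(p$explained_variance_ratio), c(0.5, 0.5), tolerance = 0.03)
})

test_that("PLS-DA decomposes X exactly and fits strong class structure", {
  set.seed(4)
  X <- matrix(rnorm(15 * 6), 15, 6)
  labels <- rep(c("A", "B", "C"), each = 5)
  f <- fit_plsda(X, labels, n_components = 2, cv_seed = 1)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(f$T %*% t(f$P) + f$E, Xc, tolerance = 1e-10)
  # at full rank the X-residual vanishes
  ffull <- fit_plsda(X, labels, n_components = qr(Xc)$rank, cv_seed = 1)
  expect_lt(norm(ffull$E, "F") / norm(Xc, "F"), 1e-8)
  # R2Y never decreases with components
  r2 <- sapply(1:5, function(k)
    fit_plsda(X, labels, n_components = k, cv_seed = 1)$R2Y)
  expect_true(all(diff(r2) >= -1e-10))
  expect_error(fit_plsda(X, rep("A", 15)), "classes")
  expect_error(fit_plsda(X, labels, n_components = 50), "rank")
})

test_that("strong-signal synthetic data yields high R2Y and positive Q2", {
  ft <- generate_feature_table(strong_spec(1))
  z <- normalize_zscore(ft)
  f <- fit_plsda(z, ft$origins, n_components = 3, cv_seed = 1)
  expect_gte(f$R2Y, 0.9)
  expect_gt(f$Q2, 0.5)
})

test_that("multivariate fits are invariant to sample order", {
  ft <- generate_feature_table(synthetic_spec(n_per_class = 5, seed = 6))
  z <- normalize_zscore(ft)$values
  perm <- sample(nrow(z))
  p1 <- fit_pca(z, 2); p2 <- fit_pca(z[perm, ], 2)
  expect_equal(p2$scores, p1$scores[perm, ], tolerance = 1e-8)
  f1 <- fit_plsda(z, ft$origins, cv_seed = 1)
  f2 <- fit_plsda(z[perm, ], ft$origins[perm], cv_seed = 1)
  expect_equal(f2$R2Y, f1$R2Y, tolerance = 1e-8)
})

test_that("permutation test separates signal from label noise", {
  ft <- generate_feature_table(strong_spec(2))
  z <- normalize_zscore(ft)
  pt <- permutation_test_plsda(z, ft$origins, n_perm = 30, seed = 1)
  expect_gt(pt$Q2, max(pt$permutations$Q2))
  expect_lt(pt$q2_intercept, pt$Q2)
  pt2 <- permutation_test_plsda(z, ft$origins, n_perm = 30, seed = 1)
  expect_identical(pt$r2_intercept, pt2$r2_intercept)
  expect_identical(pt$q2_intercept, pt2$q2_intercept)
  expect_error(permutation_test_plsda(z, ft$origins, n_perm = 5), "n_perm")
})

test_that("pure-noise data gives an unpermuted Q2 inside the null band", {
  set.seed(7)
  X <- matrix(rnorm(30 * 20), 30, 20)
  labels <- rep(c("A", "B", "C"), each = 10)
  pt <- permutation_test_plsda(X, labels, n_perm = 50, seed = 2)
  band <- quantile(pt$permutations$Q2, c(0.05, 0.95))
  expect_gte(pt$Q2, band[1])
  expect_lte(pt$Q2, band[2])
})
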