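test_that("kernel evaluations match closed forms", {
  expect_equal(kernel_eval(c(1, 2), c(1, 2), "rbf", gamma = 0.7), 1)
  expect_equal(kernel_eval(0, 1, "rbf", gamma = log(2)), 0.5)
  expect_equal(kernel_eval(c(1, 2), c(3, 4), "linear"), 11)
  expect_error(kernel_eval(c(1, 2), c(1, 2, 3)), "dimension")
  expect_error(kernel_eval(0, 1, "rbf", gamma = -1), "gamma")
})

test_that("the two-point problem solves exactly by hand", {
  X <- matrix(c(-1, 1), ncol = 1)
  fit <- fit_binary_svm(X, c(-1, 1), C = 10, kernel = "linear", tol = 1e-8)
  expect_equal(fit$alpha, c(0.5, 0.5), tolerance = 1e-7)
  expect_equal(fit$b, 0, tolerance = 1e-7)
  expect_equal(predict(fit, X), c(-1, 1), tolerance = 1e-6)
  expect_equal(fit$objective, 0.5, tolerance = 1e-7)
  expect_error(fit_binary_svm(X, c(1, 1), C = 1), "classes")
  expect_error(fit_binary_svm(X, c(0, 1), C = 1), "-1")
})

test_that("an RBF machine separates the XOR pattern", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(1, 1, -1, -1)
  fit <- fit_binary_svm(X, y, C = 10, kernel = "rbf", gamma = 1, tol = 1e-8)
  expect_equal(sign(predict(fit, X)), y)
  o <- qp_oracle(rbf_K(X, gamma = 1), y, C = 10)
  expect_equal(fit$objective, o$objective, tolerance = 1e-6)
})

test_that("the SMO solution matches the enumeration oracle on random problems", {
  set.seed(10)
  for (r in 1:12) {
    n <- sample(3:6, 1)
    X <- matrix(rnorm(2 * n), n, 2)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    C <- sample(c(0.5, 1, 10), 1)
    gamma <- sample(c(0.5, 1), 1)
    fit <- fit_binary_svm(X, y, C = C, kernel = "rbf", gamma = gamma,
                          tol = 1e-9, max_iter = 1e6)
    K <- rbf_K(X, gamma = gamma)
    o <- qp_oracle(K, y, C)
    expect_equal(fit$objective, o$objective, tolerance = 1e-6)
    Xt <- matrix(rnorm(20), 10, 2)
    fo <- oracle_decision(rbf_K(Xt, X, gamma), o$alpha, y, K, C)
    fm <- predict(fit, Xt)
    clear <- abs(fo) > 1e-3
    expect_equal(sign(fm[clear]), sign(fo[clear]))
  }
})

test_that("KKT conditions hold at the fitted solution", {
  set.seed(11)
  for (r in 1:6) {
    X <- matrix(rnorm(40), 20, 2)
    y <- ifelse(X[, 1] + 0.5 * rnorm(20) > 0, 1, -1)
    if (length(unique(y)) < 2) next
    tol <- 1e-4
    fit <- fit_binary_svm(X, y, C = 5, kernel = "rbf", gamma = 0.5, tol = tol)
    a <- fit$alpha_full
    f <- predict(fit, X)
    margin <- y * f
    free <- a > 1e-7 & a < 5 - 1e-7
    expect_true(all(abs(margin[free] - 1) <= 10 * tol))
    expect_true(all(margin[a <= 1e-7] >= 1 - 10 * tol))
    expect_true(all(margin[a >= 5 - 1e-7] <= 1 + 10 * tol))
    expect_lt(abs(sum(fit$alpha * fit$y)), 1e-8)
    expect_true(all(fit$alpha > 1e-12 & fit$alpha <= 5 + 1e-12))
  }
})

test_that("one-vs-one multiclass reduces, separates blobs, and renames cleanly", {
  set.seed(12)
  X2 <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 4), 10, 2))
  lab2 <- rep(c("x", "y"), each = 10)
  m2 <- fit_multiclass_svm(X2, lab2, C = 10, gamma = 0.5)
  expect_length(m2$pairs, 1L)
  bin <- fit_binary_svm(X2, ifelse(lab2 == "x", 1, -1), C = 10, gamma = 0.5)
  expect_equal(predict(m2, X2), ifelse(predict(bin, X2) >= 0, "x", "y"))

  X3 <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 5), 10, 2),
              cbind(rnorm(10, 0), rnorm(10, 5)))
  lab3 <- rep(c("JL", "LN", "HLJ"), each = 10)
  m3 <- fit_multiclass_svm(X3, lab3, C = 10, gamma = 0.5)
  expect_equal(predict(m3, X3), lab3)

  ren <- c(JL = "c1", LN = "c2", HLJ = "c3")
  m3r <- fit_multiclass_svm(X3, unname(ren[lab3]), C = 10, gamma = 0.5)
  expect_equal(predict(m3r, X3), unname(ren[predict(m3, X3)]))
})

test_that("stratified folds are balanced, seeded and validated", {
  labels <- rep(c("a", "b", "c"), c(12, 6, 6))
  f1 <- make_folds(labels, 6, seed = 3)
  f2 <- make_folds(labels, 6, seed = 3)
  expect_identical(f1, f2)
  expect_true(all(table(f1) == 4))
  per_class <- table(labels, f1)
  expect_true(all(per_class["a", ] == 2))
  expect_error(make_folds(labels, 30), "k")
})

test_that("cross-validation is honest, seeded and near chance under shuffling", {
  ft <- generate_feature_table(strong_spec(3))
  z <- normalize_zscore(ft)
  cv1 <- cross_validate(z, ft$origins, C = 1, gamma = 0.03, seed = 4)
  cv2 <- cross_validate(z, ft$origins, C = 1, gamma = 0.03, seed = 4)
  expect_identical(cv1$predicted, cv2$predicted)
  expect_gte(cv1$accuracy, 0.9)
  chance <- sapply(1:20, function(s) {
    set.seed(s + 500)
    cross_validate(z$values, sample(ft$origins), seed = s)$accuracy
  })
  expect_lt(abs(mean(chance) - 1/3), 0.15)
  expect_error(cross_validate(z$values[1:3, ], c("a", "b", "c")), "members")
})

test_that("grid search picks the accuracy maximum with conservative ties", {
  ft <- generate_feature_table(strong_spec(2))
  z <- normalize_zscore(ft)
  g1 <- grid_search(z, ft$origins, C_grid = 1, gamma_grid = 0.03, seed = 1)
  expect_equal(c(g1$best_C, g1$best_gamma), c(1, 0.03))
  # separable data gives a broad plateau near the optimum
  gs <- grid_search(z, ft$origins, seed = 2)
  expect_gt(mean(gs$surface$accuracy >= gs$best_accuracy - 0.02), 0.5)
  expect_true(all(gs$surface$accuracy >= 0 & gs$surface$accuracy <= 1))
  expect_equal(max(gs$surface$accuracy), gs$best_accuracy)
  # a tie between C values resolves to the smaller C, then smaller gamma
  tie <- grid_search(z, ft$origins, C_grid = c(10, 1), gamma_grid = c(0.03, 0.01),
                     seed = 2)
  cands <- tie$surface[tie$surface$accuracy >= tie$best_accuracy - 1e-12, ]
  expect_equal(tie$best_C, min(cands$C))
})

test_that("models survive JSON serialization", {
  ft <- generate_feature_table(synthetic_spec(n_per_class = 4, seed = 8))
  z <- normalize_zscore(ft)
  m <- fit_multiclass_svm(z$values, ft$origins, C = 1, gamma = 0.03)
  path <- withr::local_tempfile(fileext = ".json")
  write_svm_model(m, path)
  m2 <- read_svm_model(path)
  expect_equal(predict(m2, z$values), predict(m, z$values))
})

test_that("Z-scoring beats raw input when feature scales are heterogeneous", {
  wins <- 0; gains <- numeric(0)
  for (s in 1:10) {
    spec <- synthetic_spec(n_per_class = 10, effect_size = 2,
                           scale_spread = 1e3, seed = s)
    ft <- generate_feature_table(spec)
    raw <- cross_validate(ft, C = 1, gamma = 0.03, seed = s)$accuracy
    zs <- cross_validate(normalize_zscore(ft), ft$origins, C = 1,
                         gamma = 0.03, seed = s)$accuracy
    wins <- wins + (zs >= raw)
    gains <- c(gains, zs - raw)
  }
  expect_gte(wins, 9)
  expect_gt(mean(gains), 0.05)
})
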