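test_that("importance is seeded, shaped and zero for a no-change permutation", {
  set.seed(20)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("F1", "F2", "F3")))
  lab <- rep(c("A", "B"), each = 10)
  r1 <- permutation_importance(x, lab, N = 3, k = 5, seed = 2)
  r2 <- permutation_importance(x, lab, N = 3, k = 5, seed = 2)
  expect_identical(r1$importance, r2$importance)
  expect_equal(dim(r1$perm_scores), c(3L, 3L))
  expect_equal(r1$importance$imp, unname(r1$baseline - rowMeans(r1$perm_scores)),
               tolerance = 1e-12)
  # a constant column is invariant under permutation: importance exactly 0
  xc <- cbind(x, F4 = rep(1, 20))
  rc <- permutation_importance(xc, lab, N = 2, k = 5, seed = 2)
  expect_equal(rc$importance$imp[rc$importance$feature == "F4"], 0)
  # the raw-sum aggregation differs from the mean for N > 1
  rs <- permutation_importance(x, lab, N = 3, k = 5, seed = 2, aggregate = "sum")
  expect_equal(rs$importance$imp, r1$baseline - 3 * (r1$baseline - r1$importance$imp),
               tolerance = 1e-12)
  expect_error(permutation_importance(x, lab, N = 0), "N")
})

test_that("a single decisive feature earns a large positive importance", {
  set.seed(21)
  x <- cbind(6 * rep(1:3, each = 10) + rnorm(30, 0, 0.1),
             matrix(rnorm(270), 30, 9))
  colnames(x) <- sprintf("F%02d", 1:10)
  lab <- rep(c("A", "B", "C"), each = 10)
  r <- permutation_importance(x, lab, C = 1, gamma = 0.03, N = 20, seed = 3)
  imp <- r$importance
  expect_equal(imp$feature[imp$rank == 1], "F01")
  expect_gt(imp$imp[imp$feature == "F01"], 0.2)  # ~ s - 1/3
  expect_lt(median(abs(imp$imp[imp$feature != "F01"])), 0.1)
})

test_that("label-independent data gives importances scattered around zero", {
  imps <- unlist(lapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(300), 30, 10, dimnames = list(NULL, sprintf("F%02d", 1:10)))
    r <- permutation_importance(x, rep(c("A", "B", "C"), each = 10),
                                N = 20, seed = s)
    r$importance$imp
  }))
  expect_lt(abs(mean(imps)), 0.05)
  expect_gt(mean(abs(imps) <= 0.15), 0.95)
  expect_true(all(abs(imps) <= 0.25))
})

test_that("marker selection keeps strictly positive importances in rank order", {
  rep_fake <- structure(list(
    baseline = 0.9,
    importance = data.frame(feature = c("F1", "F2", "F3"),
                            imp = c(0.2, 0, -0.1),
                            rank = c(1L, 2L, 3L),
                            selected = c(TRUE, FALSE, FALSE)),
    N = 1L, seed = 1L), class = "importance_report")
  expect_equal(select_markers(rep_fake), "F1")
  rep_none <- rep_fake
  rep_none$importance$imp <- c(-0.1, 0, -0.2)
  rep_none$importance$selected <- rep(FALSE, 3)
  expect_warning(sel <- select_markers(rep_none), "empty")
  expect_length(sel, 0L)
})

test_that("planted markers dominate the importance ranking", {
  top_hits <- sapply(1:10, function(s) {
    ft <- generate_feature_table(synthetic_spec(n_per_class = 10, seed = s))
    z <- normalize_zscore(ft)
    r <- permutation_importance(z, ft$origins, N = 10, seed = s)
    truth <- attr(ft, "truth")$informative
    ranked <- match(r$importance$feature[order(r$importance$rank)],
                    colnames(ft$areas))
    sum(ranked[1:6] %in% truth)
  })
  expect_gte(mean(top_hits >= 4), 0.8)
  expect_gte(mean(top_hits), 4)
})

test_that("integer accuracy truncates rather than rounds", {
  expect_equal(accuracy_from_pairs(c("a", "a", "a"), c("a", "a", "b")), 66L)
  expect_equal(accuracy_from_pairs(rep("a", 4), rep("a", 4)), 100L)
  expect_equal(accuracy_from_pairs(c(rep("a", 26), rep("b", 5)),
                                   rep("a", 31)), 83L)
  expect_error(accuracy_from_pairs(character(0), character(0)), "nonempty")
  expect_error(accuracy_from_pairs(c("a", "b"), "a"), "length")
})

test_that("refitting on all features reproduces the full-table fit", {
  ft <- generate_feature_table(synthetic_spec(n_per_class = 5, seed = 9))
  z <- normalize_zscore(ft)
  grid_C <- c(1, 10); grid_g <- c(0.03, 0.001)
  all_feats <- colnames(ft$areas)
  r <- refit_on_markers(z, ft$origins, all_feats, C_grid = grid_C,
                        gamma_grid = grid_g, seed = 5)
  gs <- grid_search(z, ft$origins, C_grid = grid_C, gamma_grid = grid_g,
                    seed = 5)
  expect_equal(r$grid$surface, gs$surface)
  cv <- cross_validate(z, ft$origins, C = gs$best_C, gamma = gs$best_gamma,
                       seed = 5)
  expect_equal(r$report$pairs$recognized, cv$predicted)
  expect_error(refit_on_markers(z, ft$origins, character(0)), "markers")
  expect_error(refit_on_markers(z, ft$origins, "NOPE"), "NOPE")
})

test_that("a model restricted to the true markers classifies perfectly", {
  ft <- generate_feature_table(synthetic_spec(n_per_class = 10, seed = 13))
  z <- normalize_zscore(ft)
  truth <- colnames(ft$areas)[attr(ft, "truth")$informative]
  r <- refit_on_markers(z, ft$origins, truth, C_grid = c(1, 10),
                        gamma_grid = c(0.03, 0.3), seed = 7)
  expect_equal(r$report$accuracy, 100L)
  # a single uninformative marker is at chance
  noise <- setdiff(colnames(ft$areas), truth)[1]
  rn <- refit_on_markers(z, ft$origins, noise, C_grid = 1, gamma_grid = 0.03,
                         seed = 7)
  expect_lt(rn$report$accuracy, 60L)
})

test_that("external prediction uses training statistics and marker columns", {
  spec <- synthetic_spec(n_per_class = 10, seed = 14)
  ft <- generate_feature_table(spec)
  z <- normalize_zscore(ft)
  truth <- colnames(ft$areas)[attr(ft, "truth")$informative]
  r <- refit_on_markers(z, ft$origins, truth, C_grid = c(1, 10),
                        gamma_grid = c(0.03, 0.3), seed = 7)
  # feeding the training table back reproduces the refit model's calls
  back <- predict_external(r$model, ft, norm_stats = z)
  refit_pred <- predict(r$model, z$values[, truth])
  expect_equal(back$pairs$recognized, refit_pred)
  # held-out samples from the same feature universe are recognized
  test_ft <- generate_feature_table(spec, n_per_class = c(2, 2, 4),
                                    sample_seed = 999, sample_prefix = "T")
  rep_t <- predict_external(r$model, test_ft, norm_stats = z)
  expect_gte(rep_t$accuracy, 87L)  # at most one of 8 misassigned
  # a missing marker column is a hard error naming the column
  broken <- test_ft
  keep <- setdiff(colnames(broken$areas), truth[1])
  broken <- feature_table(broken$areas[, keep], broken$sample_ids,
                          broken$origins,
                          broken$feature_meta[match(keep, broken$feature_meta$feature), ])
  expect_error(predict_external(r$model, broken, norm_stats = NULL), truth[1])
})
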