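#' Permutation importance of every feature for the SVM
#'
#' The importance value (IV) of feature k is the drop in the model score
#' when column k is randomly permuted across samples: with baseline score
#' `s` and permuted scores `s_kn` over `N` independent repeats,
#' `imp_k = s - mean_n(s_kn)` (the raw-sum form `s - sum_n(s_kn)` of the
#' printed formula is available via `aggregate = "sum"`; for `N = 1` the two
#' coincide). The score is the mean stratified k-fold CV accuracy of the
#' one-vs-one RBF SVM at fixed (C, gamma), refit on every permuted matrix;
#' the fold assignment is held fixed so only the permutation varies.
#'
#' @param x Matrix, [feature_table()] or `normalized_table` (typically
#'   Z-scored).
#' @param labels Origin labels (taken from `x` when omitted).
#' @param C,gamma SVM hyperparameters, usually the grid-search choice.
#' @param N Permutation repeats per feature (>= 1, default 10).
#' @param k CV folds for the scorer (default 10).
#' @param seed Master seed; each (feature, repeat) permutation draws its own
#'   sub-seed, so reports are reproducible.
#' @param aggregate `"mean"` (default) or `"sum"` over repeats.
#' @return An `importance_report`: `baseline` score s, `importance` data
#'   frame (`feature`, `imp`, `rank`, `selected`), the matrix of permuted
#'   scores, `N`, and `seed`. `selected` marks `imp > 0`.
#' @export
permutation_importance <- function(x, labels = NULL, C = 1, gamma = 0.03,
                                   N = 10L, k = 10L, seed = 1L,
                                   aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (!is.numeric(N) || N < 1) stop_field("N", "must be >= 1")
  m <- as_area_matrix(x)
  labels <- table_origins(x, labels)
  p <- ncol(m)
  feats <- colnames(m)
  if (is.null(feats)) feats <- sprintf("F%04d", seq_len(p))

  folds <- make_folds(labels, k = k, seed = derive_seed(seed, 0L))
  D2 <- sq_dist(m)
  s <- cv_on_kernel(exp(-gamma * D2), labels, folds, C)$accuracy

  perm_scores <- matrix(NA_real_, p, N, dimnames = list(feats, NULL))
  n <- nrow(m)
  for (j in seq_len(p)) {
    dj <- outer(m[, j], m[, j], function(a, b) (a - b)^2)
    for (r in seq_len(N)) {
      pj <- with_seed(derive_seed(seed, j * 1000L + r), sample.int(n))
      v <- m[pj, j]
      dperm <- outer(v, v, function(a, b) (a - b)^2)
      Kp <- exp(-gamma * (D2 - dj + dperm))
      perm_scores[j, r] <- cv_on_kernel(Kp, labels, folds, C)$accuracy
    }
  }
  agg <- if (aggregate == "mean") rowMeans(perm_scores) else rowSums(perm_scores)
  imp <- s - agg
  ord <- order(-imp, seq_len(p))
  importance <- data.frame(feature = feats, imp = unname(imp), row.names = NULL)
  importance$rank <- match(seq_len(p), ord)
  importance$selected <- importance$imp > 0
  structure(list(baseline = s, importance = importance,
                 perm_scores = perm_scores, N = as.integer(N), seed = seed,
                 C = C, gamma = gamma, k = k, aggregate = aggregate),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("<importance_report> baseline accuracy %.3f, N = %d; %d/%d features with IV > 0\n",
              x$baseline, x$N, sum(x$importance$selected), nrow(x$importance)))
  invisible(x)
}

#' Select quality markers by positive importance value
#'
#' Features with strictly positive importance, ordered from highest to
#' lowest contribution.
#'
#' @param report An [permutation_importance()] report.
#' @return Character vector of marker feature names (possibly empty, with a
#'   warning).
#' @export
select_markers <- function(report) {
  stopifnot(inherits(report, "importance_report"))
  imp <- report$importance
  sel <- imp[imp$selected, , drop = FALSE]
  if (nrow(sel) == 0L) {
    warning("no feature has importance > 0; returning empty marker set")
    return(character(0))
  }
  sel$feature[order(-sel$imp, match(sel$feature, imp$feature))]
}

#' Classification report (actual vs recognized origins)
#'
#' @param sample Sample identifiers.
#' @param actual,recognized Actual and predicted origin labels.
#' @return A `classification_report`: the pairs plus the truncated integer
#'   accuracy percent from [accuracy_from_pairs()].
#' @export
classification_report <- function(sample, actual, recognized) {
  pairs <- data.frame(sample = sample, actual = as.character(actual),
                      recognized = as.character(recognized))
  structure(list(pairs = pairs,
                 accuracy = accuracy_from_pairs(pairs$actual, pairs$recognized)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  print(x$pairs, row.names = FALSE)
  cat(sprintf("Accuracy = %d%%\n", x$accuracy))
  invisible(x)
}

#' Integer percent accuracy from (actual, recognized) pairs
#'
#' Truncates (rather than rounds) to a whole percent: 26 correct of 31 gives
#' 83, matching how such tables are reported.
#'
#' @param actual Actual labels, or a 2-column data frame of pairs.
#' @param recognized Predicted labels (omit when `actual` is a data frame).
#' @return Integer percentage in 0..100.
#' @export
accuracy_from_pairs <- function(actual, recognized = NULL) {
  if (is.data.frame(actual)) {
    df <- actual
    cols <- intersect(c("actual", "recognized"), names(df))
    if (length(cols) == 2L) {
      recognized <- df$recognized; actual <- df$actual
    } else {
      recognized <- df[[2L]]; actual <- df[[1L]]
    }
  }
  if (length(actual) == 0L) stop_field("pairs", "must be nonempty")
  if (length(actual) != length(recognized))
    stop_field("pairs", "actual and recognized differ in length")
  as.integer(floor(100 * sum(actual == recognized) / length(actual)))
}

#' Re-fit the SVM on a marker panel
#'
#' Restricts the matrix to the selected marker columns, re-runs the (C,
#' gamma) grid search, and reports out-of-fold CV predictions for the marker
#' model together with a final model refit on all samples at the chosen
#' hyperparameters.
#'
#' @param x Matrix, [feature_table()] or `normalized_table`.
#' @param labels Origin labels (taken from `x` when omitted).
#' @param markers Nonempty vector of marker column names (or indices).
#' @param C_grid,gamma_grid,k,seed Passed to [grid_search()].
#' @return List with `model` (`svm_model` on the markers), `report`
#'   (out-of-fold [classification_report()]), `grid`
#'   (the [grid_search()] result) and `markers`.
#' @export
refit_on_markers <- function(x, labels = NULL, markers,
                             C_grid = 2^seq(-5, 15, by = 2),
                             gamma_grid = 2^seq(-15, 3, by = 2),
                             k = 10L, seed = 1L) {
  if (length(markers) == 0L) stop_field("markers", "must be nonempty")
  m <- as_area_matrix(x)
  labels <- table_origins(x, labels)
  if (is.character(markers)) {
    missing <- setdiff(markers, colnames(m))
    if (length(missing))
      stop(sprintf("marker column(s) not in table: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  mm <- m[, markers, drop = FALSE]
  gs <- grid_search(mm, labels, C_grid = C_grid, gamma_grid = gamma_grid,
                    k = k, seed = seed)
  cv <- cross_validate(mm, labels, C = gs$best_C, gamma = gs$best_gamma,
                       k = k, seed = seed)
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(nrow(m)))
  report <- classification_report(ids, labels, cv$predicted)
  model <- fit_multiclass_svm(mm, labels, C = gs$best_C, gamma = gs$best_gamma)
  model$markers <- colnames(mm)
  list(model = model, report = report, grid = gs, markers = colnames(mm))
}

#' Predict external samples from a marker model
#'
#' Transforms the held-out table with the TRAINING normalization statistics
#' (never re-estimated on the test set), restricts it to the model's marker
#' panel, and predicts origins.
#'
#' @param model An `svm_model` carrying a `markers` element (from
#'   [refit_on_markers()]).
#' @param test_table Matrix or [feature_table()] of external samples whose
#'   columns include every marker.
#' @param norm_stats Training `normalized_table` (or its
#'   center/scale/method), applied via [apply_normalization()]; `NULL` for
#'   raw input.
#' @return A [classification_report()] (accuracy only when the test table
#'   carries origin labels, otherwise `NA` pairs are reported as given).
#' @export
predict_external <- function(model, test_table, norm_stats = NULL) {
  stopifnot(inherits(model, "svm_model"))
  markers <- if (!is.null(model$markers)) model$markers else model$features
  m <- if (is.null(norm_stats)) as_area_matrix(test_table)
       else apply_normalization(norm_stats, test_table)
  missing <- setdiff(markers, colnames(m))
  if (length(missing))
    stop(sprintf("test table lacks marker column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  m <- m[, markers, drop = FALSE]
  pred <- predict(model, m)
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("T%d", seq_len(nrow(m)))
  actual <- if (inherits(test_table, "feature_table") && !is.null(test_table$origins))
    test_table$origins else rep(NA_character_, nrow(m))
  pairs <- data.frame(sample = ids, actual = actual, recognized = pred)
  if (all(is.na(actual)))
    structure(list(pairs = pairs, accuracy = NA_integer_),
              class = "classification_report")
  else classification_report(ids, actual, pred)
}
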