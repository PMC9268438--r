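#' Kernel evaluation
#'
#' @param x,z Numeric vectors of equal length.
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param gamma RBF width (> 0): `exp(-gamma * ||x - z||^2)`.
#' @return Scalar kernel value.
#' @export
kernel_eval <- function(x, z, kernel = c("rbf", "linear"), gamma = 0.03) {
  kernel <- match.arg(kernel)
  if (length(x) != length(z)) stop("dimension mismatch", call. = FALSE)
  if (kernel == "linear") return(sum(x * z))
  if (!is.numeric(gamma) || gamma <= 0) stop_field("gamma", "must be > 0 for rbf")
  exp(-gamma * sum((x - z)^2))
}

# Pairwise squared Euclidean distances between rows of X and Z.
sq_dist <- function(X, Z = X) {
  xs <- rowSums(X^2); zs <- rowSums(Z^2)
  d <- outer(xs, zs, "+") - 2 * tcrossprod(X, Z)
  d[d < 0] <- 0
  d
}

kernel_matrix <- function(X, Z = X, kernel = "rbf", gamma = 0.03) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (ncol(X) != ncol(Z)) stop("dimension mismatch", call. = FALSE)
  if (kernel == "linear") tcrossprod(X, Z) else exp(-gamma * sq_dist(X, Z))
}

#' Fit a binary soft-margin SVM from the dual
#'
#' Solves the standard C-SVM dual -- maximize `sum(alpha) - 1/2 sum alpha_i
#' alpha_j y_i y_j K(x_i, x_j)` subject to `0 <= alpha <= C` and
#' `sum(alpha * y) = 0` -- by sequential minimal optimization with
#' maximal-violating-pair selection. The bias is the average of
#' `y_j - f(x_j)` over free support vectors (`0 < alpha < C`), which sit
#' exactly on the margin at the optimum; the decision function is the kernel
#' expansion `f(x) = sum alpha_i y_i K(x_i, x) + b`. The primal weight
#' vector is materialized only for the linear kernel.
#'
#' @param X Training matrix (samples x features).
#' @param y Labels in `{-1, +1}`, both classes present.
#' @param C Box constraint (> 0).
#' @param kernel,gamma See [kernel_eval()].
#' @param tol KKT violation tolerance of the solver.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return An object of class `binary_svm`: support vectors, their dual
#'   coefficients and labels, bias `b`, the dual objective value, and the
#'   kernel configuration.
#' @export
fit_binary_svm <- function(X, y, C = 1, kernel = c("rbf", "linear"),
                           gamma = 0.03, tol = 1e-3, max_iter = 200000L) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  if (!all(y %in% c(-1, 1))) stop_field("y", "labels must be -1/+1")
  if (length(unique(y)) < 2L) stop_field("y", "both classes must be present")
  if (!is.numeric(C) || C <= 0) stop_field("C", "must be > 0")
  K <- kernel_matrix(X, kernel = kernel, gamma = gamma)
  sol <- smo_solve_cpp(K, as.numeric(y), C, tol, as.integer(max_iter))
  if (!sol$converged)
    stop(sprintf("SMO did not converge within %d iterations", sol$iterations),
         call. = FALSE)
  sv <- which(sol$alpha > 1e-12)
  w <- if (kernel == "linear")
    drop(crossprod(X[sv, , drop = FALSE], sol$alpha[sv] * y[sv])) else NULL
  structure(list(X_sv = X[sv, , drop = FALSE], alpha = sol$alpha[sv],
                 y = y[sv], b = sol$b, w = w, objective = sol$objective,
                 alpha_full = sol$alpha, iterations = sol$iterations,
                 kernel = kernel, gamma = gamma, C = C, tol = tol),
            class = "binary_svm")
}

#' Decision values of a binary SVM
#'
#' @param object A `binary_svm`.
#' @param newdata Matrix of samples to score.
#' @param ... Unused.
#' @return Numeric decision values `f(x)`; the predicted label is its sign.
#' @export
predict.binary_svm <- function(object, newdata, ...) {
  K <- kernel_matrix(as.matrix(newdata), object$X_sv,
                     kernel = object$kernel, gamma = object$gamma)
  drop(K %*% (object$alpha * object$y)) + object$b
}

#' Fit a one-vs-one multiclass SVM
#'
#' One binary dual SVM per unordered class pair. Prediction is by majority
#' vote over the pairwise decisions, ties broken by the larger summed signed
#' decision value, then by class order (order of first appearance in
#' `labels`).
#'
#' @param X Training matrix.
#' @param labels Class labels (>= 2 classes).
#' @inheritParams fit_binary_svm
#' @return An object of class `svm_model` holding the pairwise `binary_svm`
#'   fits, the class list, and the kernel configuration.
#' @export
fit_multiclass_svm <- function(X, labels, C = 1, kernel = c("rbf", "linear"),
                               gamma = 0.03, tol = 1e-3, max_iter = 200000L) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2L) stop_field("labels", "need at least two classes")
  pairs <- list()
  for (a in seq_len(length(classes) - 1L)) {
    for (b in seq((a + 1L), length(classes))) {
      idx <- labels %in% classes[c(a, b)]
      y <- ifelse(labels[idx] == classes[a], 1, -1)
      fit <- fit_binary_svm(X[idx, , drop = FALSE], y, C = C, kernel = kernel,
                            gamma = gamma, tol = tol, max_iter = max_iter)
      pairs[[length(pairs) + 1L]] <- list(pos = classes[a], neg = classes[b],
                                          fit = fit)
    }
  }
  structure(list(pairs = pairs, classes = classes, kernel = kernel,
                 gamma = gamma, C = C, features = colnames(X)),
            class = "svm_model")
}

#' Predict origins with a one-vs-one SVM
#'
#' @param object An `svm_model`.
#' @param newdata Matrix with the model's feature columns.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata)) &&
      all(object$features %in% colnames(newdata)))
    newdata <- newdata[, object$features, drop = FALSE]
  n <- nrow(newdata)
  classes <- object$classes
  votes <- matrix(0L, n, length(classes), dimnames = list(NULL, classes))
  score <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  for (pm in object$pairs) {
    dec <- predict(pm$fit, newdata)
    win <- ifelse(dec >= 0, pm$pos, pm$neg)
    votes[cbind(seq_len(n), match(win, classes))] <-
      votes[cbind(seq_len(n), match(win, classes))] + 1L
    score[, pm$pos] <- score[, pm$pos] + dec
    score[, pm$neg] <- score[, pm$neg] - dec
  }
  vapply(seq_len(n), function(i) {
    best <- which(votes[i, ] == max(votes[i, ]))
    if (length(best) > 1L) best <- best[score[i, best] == max(score[i, best])]
    classes[best[1L]]
  }, character(1))
}

#' Stratified fold assignment
#'
#' Shuffles each class separately under the seed and deals its members
#' round-robin over the folds, so classes stay balanced across folds.
#'
#' @param labels Class labels.
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..k`, aligned to `labels`.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  if (k < 2L || k > n) stop_field("k", "must satisfy 2 <= k <= n")
  folds <- integer(n)
  with_seed(seed, {
    start <- 0L
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
  })
  folds
}

# CV accuracy and out-of-fold predictions on a precomputed kernel matrix.
cv_on_kernel <- function(K, labels, folds, C, tol = 1e-3, max_iter = 200000L) {
  classes <- unique(labels)
  cls <- match(labels, classes) - 1L
  res <- svm_cv_predict_cpp(K, as.integer(cls), as.integer(folds), C, tol,
                            as.integer(max_iter))
  list(accuracy = res$accuracy, predicted = classes[res$pred + 1L])
}

#' Cross-validated accuracy of the multiclass SVM
#'
#' Stratified k-fold cross-validation: every sample is predicted by a model
#' that never saw it, and the out-of-fold predicted labels are returned --
#' the "recognized" origin column of a training report.
#'
#' @param x Matrix, [feature_table()] or `normalized_table`.
#' @param labels Class labels (taken from `x` when omitted); every class
#'   needs at least 2 members.
#' @param C,gamma SVM hyperparameters.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param kernel Kernel name.
#' @return List with `accuracy` (fraction correct), `predicted` (out-of-fold
#'   labels aligned to samples), and `folds`.
#' @export
cross_validate <- function(x, labels = NULL, C = 1, gamma = 0.03, k = 10L,
                           seed = 1L, kernel = "rbf") {
  m <- as_area_matrix(x)
  labels <- table_origins(x, labels)
  if (any(table(labels) < 2L)) stop_field("labels", "every class needs >= 2 members")
  folds <- make_folds(labels, k = k, seed = seed)
  K <- kernel_matrix(m, kernel = kernel, gamma = gamma)
  out <- cv_on_kernel(K, labels, folds, C)
  out$folds <- folds
  out
}

#' Grid search over (C, gamma) by cross-validation
#'
#' Evaluates the full accuracy surface of mean stratified k-fold CV accuracy
#' over the Cartesian grid and picks the maximizing cell; ties go to the
#' smallest C, then the smallest gamma (the weaker-regularization /
#' smoother-kernel preference). The fold assignment is fixed across cells so
#' surfaces are comparable.
#'
#' @inheritParams cross_validate
#' @param C_grid,gamma_grid Candidate values; defaults span `2^-5..2^15` and
#'   `2^-15..2^3` in log2 steps of 2.
#' @return A `grid_search_result`: `surface` data frame (`C`, `gamma`,
#'   `accuracy`), `best_C`, `best_gamma`, `best_accuracy`, `seed`.
#' @export
grid_search <- function(x, labels = NULL, C_grid = 2^seq(-5, 15, by = 2),
                        gamma_grid = 2^seq(-15, 3, by = 2), k = 10L,
                        seed = 1L) {
  if (length(C_grid) == 0 || length(gamma_grid) == 0)
    stop_field("grid", "C_grid and gamma_grid must be nonempty")
  m <- as_area_matrix(x)
  labels <- table_origins(x, labels)
  folds <- make_folds(labels, k = k, seed = seed)
  D2 <- sq_dist(m)
  surface <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid))
  surface$accuracy <- NA_real_
  for (g in sort(gamma_grid)) {
    K <- exp(-g * D2)
    for (C in sort(C_grid)) {
      acc <- cv_on_kernel(K, labels, folds, C)$accuracy
      surface$accuracy[surface$C == C & surface$gamma == g] <- acc
    }
  }
  best <- surface[surface$accuracy >= max(surface$accuracy) - 1e-12, ]
  best <- best[order(best$C, best$gamma), ][1, ]
  structure(list(surface = surface, best_C = best$C, best_gamma = best$gamma,
                 best_accuracy = best$accuracy, k = k, seed = seed),
            class = "grid_search_result")
}

#' Serialize / restore an SVM model as JSON
#'
#' Stores dual coefficients, support vectors, labels, biases and the kernel
#' configuration in a documented JSON layout.
#'
#' @param model An `svm_model`.
#' @param path Output JSON path.
#' @return `write_svm_model` returns `path` invisibly; `read_svm_model` the
#'   restored `svm_model`.
#' @export
write_svm_model <- function(model, path) {
  stopifnot(inherits(model, "svm_model"))
  payload <- list(
    classes = model$classes, kernel = model$kernel, gamma = model$gamma,
    C = model$C, features = model$features,
    pairs = lapply(model$pairs, function(pm) list(
      pos = pm$pos, neg = pm$neg, b = pm$fit$b, alpha = pm$fit$alpha,
      y = pm$fit$y, support_vectors = unname(as.matrix(pm$fit$X_sv)))))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- lapply(seq_len(nrow(p$pairs)), function(i) {
    sv <- p$pairs$support_vectors[[i]]
    colnames(sv) <- p$features
    list(pos = p$pairs$pos[i], neg = p$pairs$neg[i],
         fit = structure(list(X_sv = sv, alpha = p$pairs$alpha[[i]],
                              y = p$pairs$y[[i]], b = p$pairs$b[i],
                              kernel = p$kernel, gamma = p$gamma, C = p$C),
                         class = "binary_svm"))
  })
  structure(list(pairs = pairs, classes = p$classes, kernel = p$kernel,
                 gamma = p$gamma, C = p$C, features = p$features),
            class = "svm_model")
}
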