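as_area_matrix <- function(x) {
  if (inherits(x, "feature_table")) x$areas
  else if (inherits(x, "normalized_table")) x$values
  else as.matrix(x)
}

table_origins <- function(x, labels = NULL) {
  if (!is.null(labels)) return(as.character(labels))
  if (inherits(x, "feature_table") || inherits(x, "normalized_table")) {
    if (is.null(x$origins)) stop("no origin labels available", call. = FALSE)
    return(as.character(x$origins))
  }
  stop("labels must be supplied for a plain matrix", call. = FALSE)
}

new_normalized_table <- function(values, method, center, scale, template) {
  structure(list(values = values, method = method, center = center,
                 scale = scale,
                 sample_ids = rownames(values),
                 origins = if (inherits(template, "feature_table") ||
                               inherits(template, "normalized_table"))
                   template$origins else NULL),
            class = "normalized_table")
}

#' Mean normalization
#'
#' Divides every feature column by its mean over samples, so each feature
#' has mean 1 and the heterogeneous per-feature intensity scales cancel.
#'
#' @param x A [feature_table()], `normalized_table`, or numeric matrix
#'   (samples x features).
#' @return A `normalized_table` with `method = "mean"` and the per-feature
#'   means stored in `$scale`.
#' @export
normalize_mean <- function(x) {
  m <- as_area_matrix(x)
  mu <- colMeans(m)
  if (any(mu == 0)) {
    bad <- colnames(m)[mu == 0]
    stop(sprintf("zero-mean feature(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  new_normalized_table(sweep(m, 2, mu, "/"), "mean",
                       center = rep(0, ncol(m)), scale = mu, template = x)
}

#' Z-score normalization
#'
#' Centers every feature column and divides by its standard deviation,
#' converting each feature to mean 0 and unit spread so that no feature
#' dominates by scale. The population (n) denominator is the default, giving
#' exactly unit population sd per column; `denominator = "sample"` uses n-1.
#'
#' @inheritParams normalize_mean
#' @param denominator `"population"` (n) or `"sample"` (n-1).
#' @return A `normalized_table` with `method = "zscore"`, feature means in
#'   `$center` and sds in `$scale` (the statistics later applied to held-out
#'   samples).
#' @export
normalize_zscore <- function(x, denominator = c("population", "sample")) {
  denominator <- match.arg(denominator)
  m <- as_area_matrix(x)
  n <- nrow(m)
  mu <- colMeans(m)
  s2 <- colMeans(sweep(m, 2, mu)^2)
  if (denominator == "sample") s2 <- s2 * n / (n - 1)
  s <- sqrt(s2)
  if (any(s == 0)) {
    bad <- colnames(m)[s == 0]
    stop(sprintf("zero-variance feature(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  new_normalized_table(sweep(sweep(m, 2, mu), 2, s, "/"), "zscore",
                       center = mu, scale = s, template = x)
}

#' Apply stored normalization statistics to new samples
#'
#' Transforms held-out data with the training-set statistics (never
#' re-estimated), as required when predicting external samples.
#'
#' @param stats A `normalized_table` (its `$center`/`$scale`/`$method`), or a
#'   list with those elements.
#' @param newdata Matrix or [feature_table()] whose columns are named like the
#'   training features (any order, supersets allowed).
#' @return Numeric matrix of transformed values, columns in training order.
#' @export
apply_normalization <- function(stats, newdata) {
  m <- as_area_matrix(newdata)
  feats <- names(stats$scale)
  if (!is.null(feats)) {
    missing <- setdiff(feats, colnames(m))
    if (length(missing))
      stop(sprintf("test table lacks feature(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    m <- m[, feats, drop = FALSE]
  }
  switch(stats$method,
         mean = sweep(m, 2, stats$scale, "/"),
         zscore = sweep(sweep(m, 2, stats$center), 2, stats$scale, "/"),
         none = m,
         stop("unknown normalization method", call. = FALSE))
}

#' Principal component analysis by covariance eigendecomposition
#'
#' Column-centers the matrix, eigendecomposes its sample covariance and
#' orders components by decreasing eigenvalue. The sign of each loading
#' vector is fixed so its largest-magnitude element is positive.
#'
#' @param x Matrix, [feature_table()] or `normalized_table`.
#' @param n_components Number of components, at most
#'   `min(n_samples - 1, n_features)`.
#' @return A `pca_result` with orthonormal `loadings` (features x
#'   components), `scores` (= centered data times loadings),
#'   `explained_variance_ratio`, and the eigenvalues.
#' @export
fit_pca <- function(x, n_components = 2L) {
  m <- as_area_matrix(x)
  n <- nrow(m); p <- ncol(m)
  kmax <- min(n - 1L, p)
  if (!is.numeric(n_components) || n_components < 1 || n_components > kmax)
    stop_field("n_components", sprintf("must be in 1..%d", kmax))
  xc <- sweep(m, 2, colMeans(m))
  ev <- eigen(cov(xc), symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  k <- as.integer(n_components)
  load <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(m)
  scores <- xc %*% load
  structure(list(loadings = load, scores = scores,
                 eigenvalues = vals[seq_len(k)],
                 explained_variance_ratio = vals[seq_len(k)] / sum(vals),
                 center = colMeans(m)),
            class = "pca_result")
}

one_hot <- function(labels, classes = unique(labels)) {
  y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  y[cbind(seq_along(labels), match(labels, classes))] <- 1
  y
}

# NIPALS PLS2 on centered matrices; returns weights/scores/loadings and
# residuals. Deflation X <- X - t p', Y <- Y - t q' makes X = T P' + E exact.
pls_nipals <- function(Xc, Yc, ncomp, tol = 1e-12, max_iter = 500L) {
  n <- nrow(Xc); p <- ncol(Xc); q <- ncol(Yc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp); Tt <- matrix(0, n, ncomp); U <- matrix(0, n, ncomp)
  E <- Xc; F_ <- Yc
  for (a in seq_len(ncomp)) {
    u <- F_[, which.max(colSums(F_^2))]
    if (sum(u^2) < 1e-30) u <- E[, which.max(colSums(E^2))]
    w_old <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(E, u))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-30) stop("PLS component degenerate (rank exceeded)", call. = FALSE)
      w <- w / nw
      tt <- drop(E %*% w)
      qq <- drop(crossprod(F_, tt)) / sum(tt^2)
      u <- drop(F_ %*% qq) / sum(qq^2)
      if (sum((w - w_old)^2) < tol) break
      w_old <- w
    }
    pp <- drop(crossprod(E, tt)) / sum(tt^2)
    E <- E - tcrossprod(tt, pp)
    F_ <- F_ - tcrossprod(tt, qq)
    W[, a] <- w; P[, a] <- pp; Q[, a] <- qq; Tt[, a] <- tt; U[, a] <- u
  }
  list(W = W, P = P, Q = Q, T = Tt, U = U, E = E, F = F_)
}

pls_coefficients <- function(fit) {
  # regression coefficients mapping centered X to centered Y
  fit$W %*% solve(crossprod(fit$P, fit$W), t(fit$Q))
}

#' Partial least squares discriminant analysis
#'
#' Fits a PLS2 model by NIPALS between the (centered) data matrix and the
#' centered one-hot origin matrix, extracting latent components that maximize
#' the covariance between the X- and Y-scores, with deflation after each
#' component: `X = T P' + E`, `Y = U Q' + F`. Reports the fraction of label
#' variance explained (R2Y) and the cross-validated predictive ability (Q2)
#' from stratified k-fold prediction error.
#'
#' @param x Matrix, [feature_table()] or `normalized_table`.
#' @param labels Origin labels (taken from `x` when omitted).
#' @param n_components Latent components; default `number of classes - 1`.
#' @param cv_folds Folds for Q2 (default 10, stratified).
#' @param cv_seed Seed for the fold assignment.
#' @return A `plsda_result` with scores `T`/`U`, loadings `P`/`Q`, weights
#'   `W`, residuals `E`/`F`, `R2Y`, `Q2`, class list and centering info.
#' @export
fit_plsda <- function(x, labels = NULL, n_components = NULL,
                      cv_folds = 10L, cv_seed = 1L) {
  m <- as_area_matrix(x)
  labels <- table_origins(x, labels)
  classes <- unique(labels)
  if (length(classes) < 2L) stop_field("labels", "need at least two classes")
  if (is.null(n_components)) n_components <- length(classes) - 1L
  xc_means <- colMeans(m)
  Xc <- sweep(m, 2, xc_means)
  rk <- qr(Xc)$rank
  if (n_components > rk)
    stop_field("n_components", sprintf("exceeds rank %d of the centered matrix", rk))
  Y <- one_hot(labels, classes)
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2, y_means)

  fit <- pls_nipals(Xc, Yc, n_components)
  r2y <- 1 - sum(fit$F^2) / sum(Yc^2)

  folds <- make_folds(labels, k = min(cv_folds, nrow(m)), seed = cv_seed)
  press <- 0; tss <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    mtr <- colMeans(m[tr, , drop = FALSE])
    ymtr <- colMeans(Y[tr, , drop = FALSE])
    Xtr <- sweep(m[tr, , drop = FALSE], 2, mtr)
    Ytr <- sweep(Y[tr, , drop = FALSE], 2, ymtr)
    nc_f <- min(n_components, qr(Xtr)$rank)
    ftr <- pls_nipals(Xtr, Ytr, nc_f)
    B <- pls_coefficients(ftr)
    Yhat <- sweep(m[te, , drop = FALSE], 2, mtr) %*% B
    Yte <- sweep(Y[te, , drop = FALSE], 2, ymtr)
    press <- press + sum((Yte - Yhat)^2)
    tss <- tss + sum(Yte^2)
  }
  q2 <- 1 - press / tss

  structure(list(T = fit$T, U = fit$U, P = fit$P, Q = fit$Q, W = fit$W,
                 E = fit$E, F = fit$F, n_components = n_components,
                 R2Y = r2y, Q2 = q2, classes = classes,
                 x_center = xc_means, y_center = y_means,
                 coefficients = pls_coefficients(fit)),
            class = "plsda_result")
}

#' Label-permutation test for a PLS-DA model
#'
#' Refits the model on randomly permuted origin labels, recording for each
#' permutation the correlation between the permuted and original (centered,
#' one-hot) label matrices together with the permuted R2 and Q2. Intercepts
#' at correlation 0 come from least-squares lines through the permuted
#' points plus the unpermuted point at correlation 1 -- the usual
#' chemometrics overfitting diagnostic: intercepts well below the real R2Y
#' and Q2 indicate genuine class structure.
#'
#' @inheritParams fit_plsda
#' @param n_perm Number of label permutations (>= 20).
#' @param seed Seed controlling the permutations (and the Q2 folds).
#' @return List with the unpermuted `R2Y`/`Q2`, a `permutations` data frame
#'   (`correlation`, `R2`, `Q2`), and `r2_intercept` / `q2_intercept`.
#' @export
permutation_test_plsda <- function(x, labels = NULL, n_perm = 100L, seed = 1L,
                                   n_components = NULL, cv_folds = 10L) {
  if (n_perm < 20L) stop_field("n_perm", "need at least 20 permutations")
  m <- as_area_matrix(x)
  labels <- table_origins(x, labels)
  base <- fit_plsda(m, labels, n_components = n_components,
                    cv_folds = cv_folds, cv_seed = derive_seed(seed, 0L))
  Y0 <- scale(one_hot(labels, base$classes), scale = FALSE)

  res <- with_seed(derive_seed(seed, 1L), {
    t(vapply(seq_len(n_perm), function(i) {
      perm <- sample(length(labels))
      pl <- labels[perm]
      f <- fit_plsda(m, pl, n_components = base$n_components,
                     cv_folds = cv_folds, cv_seed = derive_seed(seed, 1L + i))
      Yp <- scale(one_hot(pl, base$classes), scale = FALSE)
      c(correlation = cor(as.vector(Yp), as.vector(Y0)), R2 = f$R2Y, Q2 = f$Q2)
    }, numeric(3)))
  })
  perms <- as.data.frame(res)
  pts <- rbind(perms,
               data.frame(correlation = 1, R2 = base$R2Y, Q2 = base$Q2))
  r2_int <- unname(coef(lm(R2 ~ correlation, data = pts))[1])
  q2_int <- unname(coef(lm(Q2 ~ correlation, data = pts))[1])
  list(R2Y = base$R2Y, Q2 = base$Q2, permutations = perms,
       r2_intercept = r2_int, q2_intercept = q2_int, n_perm = n_perm,
       seed = seed)
}
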