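#' Gaussian (RBF) kernel
#'
#' `K(a, b) = exp(-gamma * ||a - b||^2)` with the Euclidean norm; `gamma`
#' is the kernel width. Symmetric and in `(0, 1]`.
#'
#' @param a,b Numeric vectors of equal length.
#' @param gamma Kernel width, `>= 0`.
#' @return A single number.
#' @examples
#' rbf_kernel(c(0, 0), c(1, 1), 0.5)  # exp(-1)
#' @export
rbf_kernel <- function(a, b, gamma) {
  if (length(a) != length(b))
    stop("kernel arguments must have equal dimension")
  assert_scalar_number(gamma, "gamma")
  if (gamma < 0) stop_config("gamma must be >= 0")
  exp(-gamma * sum((a - b)^2))
}

# n x m cross-kernel matrix between rows of A and rows of B.
rbf_cross <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Train a soft-margin RBF-kernel SVM
#'
#' Solves the soft-margin dual problem for the Gaussian kernel (the
#' quadratic program is delegated to the LIBSVM solver in \pkg{e1071});
#' the returned model stores everything needed to evaluate the decision
#' function `f(x) = sum_i y_i alpha_i K(x_i, x) + b` on its own: support
#' vectors, dual coefficients `y_i alpha_i`, bias, kernel width, and the
#' feature subset and scaling the model expects.
#'
#' @param m Labeled, standardized [feature_matrix()] with both classes.
#' @param C Regularization parameter, `> 0`.
#' @param gamma Kernel width, `> 0`.
#' @param scaling Optional standardizer parameters (stored verbatim so
#'   prediction can reproduce the training-time transform).
#' @return An object of class `lux_svm` with fields `gamma`, `C`, `SV`
#'   (support vectors, rows), `dual_coefs` (`y_i alpha_i`), `bias`,
#'   `feature_ids`, `scaling`.
#' @export
train_svm <- function(m, C, gamma, scaling = NULL) {
  stopifnot(inherits(m, "feature_matrix"))
  y <- assert_labels(m$y)
  assert_scalar_number(C, "C", positive = TRUE)
  assert_scalar_number(gamma, "gamma", positive = TRUE)
  if (any(!is.finite(m$X))) stop("non-finite features")
  yf <- factor(y, levels = c(1L, -1L))
  fit <- e1071::svm(m$X, yf, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE, shrinking = FALSE)
  # LIBSVM orients the decision function toward whichever class appears
  # first in the training data; flip so that f > 0 always means class +1
  orient <- if (identical(fit$levels[fit$labels[1L]], "1")) 1 else -1
  model <- structure(list(
    gamma = gamma, C = C,
    SV = unname(fit$SV),
    dual_coefs = orient * as.numeric(fit$coefs),
    bias = -orient * fit$rho,
    feature_ids = m$feature_ids,
    scaling = scaling), class = "lux_svm")
  model
}

#' @export
print.lux_svm <- function(x, ...) {
  cat("<lux_svm> RBF SVM:", nrow(x$SV), "support vectors,",
      length(x$feature_ids), "features, C =", x$C, ", gamma =", x$gamma, "\n")
  invisible(x)
}

#' Evaluate the SVM decision function
#'
#' `decision_value()` computes `f(x) = sum_i y_i alpha_i K(x_i, x) + b`
#' from the stored model fields; `predict_label()` returns the class by
#' the sign of `f(x)`, with `f(x) = 0` mapped to `-1`.
#'
#' @param model A `lux_svm` model.
#' @param X Numeric vector (one instance) or matrix (instances in rows)
#'   in the model's feature space (already subset and scaled).
#' @return `decision_value()`: numeric vector of decision values;
#'   `predict_label()`: integer labels in `{+1, -1}`.
#' @export
decision_value <- function(model, X) {
  stopifnot(inherits(model, "lux_svm"))
  if (nrow(model$SV) == 0L) stop("model has no support vectors")
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != ncol(model$SV))
    stop("dimension mismatch: model expects ", ncol(model$SV),
         " features, got ", ncol(X))
  K <- rbf_cross(X, model$SV, model$gamma)
  as.numeric(K %*% model$dual_coefs + model$bias)
}

#' @rdname decision_value
#' @export
predict_label <- function(model, X) {
  f <- decision_value(model, X)
  ifelse(f > 0, 1L, -1L)
}

#' Stratified k-fold assignment
#'
#' Randomly partitions indices into `k` folds so that the per-class counts
#' differ by at most one across folds; reproducible for a fixed seed.
#'
#' @param y Labels in `{+1, -1}`.
#' @param k Number of folds, `>= 2`; every class must have `>= k` members.
#' @param seed Integer seed controlling the assignment.
#' @return Integer vector of fold ids (1..k), one per instance.
#' @export
stratified_kfold <- function(y, k = 5L, seed = 1L) {
  y <- assert_labels(y)
  k <- as.integer(k)
  if (k < 2L) stop_config("k must be >= 2")
  if (any(table(y) < k))
    stop_config("every class needs at least k = ", k, " members")
  folds <- integer(length(y))
  set.seed(seed)
  for (cl in c(-1L, 1L)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Grid search over (C, gamma) with stratified cross-validated accuracy
#'
#' For every pair on the grid the data are split into `k` stratified
#' folds; each fold in turn is held out, an SVM is trained on the rest,
#' and the held-out accuracy is recorded. The pair's score is the average
#' accuracy over the `k` folds, in percent. Among pairs whose score ties
#' the maximum, the smallest `C` wins (preferring low model complexity),
#' then the smallest `gamma`. The default lattice is the standard
#' LIBSVM-guide grid `C = 2^(-5, -3, ..., 15)`,
#' `gamma = 2^(-15, -13, ..., 3)`.
#'
#' @param m Labeled, standardized [feature_matrix()].
#' @param C_grid,gamma_grid Candidate values, non-empty.
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @return A list of class `lux_grid_search` with `grid` (data frame of
#'   `C`, `gamma`, `cv_accuracy` in percent), `best_C`, `best_gamma`,
#'   `best_accuracy`, `k`, `seed`.
#' @export
grid_search_cv <- function(m, C_grid = 2^seq(-5, 15, 2),
                           gamma_grid = 2^seq(-15, 3, 2), k = 5L, seed = 1L) {
  stopifnot(inherits(m, "feature_matrix"))
  y <- assert_labels(m$y)
  if (length(C_grid) < 1L || length(gamma_grid) < 1L)
    stop_config("grids must be non-empty")
  folds <- stratified_kfold(y, k = k, seed = seed)
  grid <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid),
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_accuracy <- vapply(seq_len(nrow(grid)), function(g) {
    acc <- vapply(seq_len(k), function(fold) {
      tr <- folds != fold
      fit <- train_svm(feature_matrix(m$X[tr, , drop = FALSE],
                                      m$sample_ids[tr], m$feature_ids, y[tr]),
                       C = grid$C[g], gamma = grid$gamma[g])
      mean(predict_label(fit, m$X[!tr, , drop = FALSE]) == y[!tr]) * 100
    }, 0)
    mean(acc)
  }, 0)
  # tie tolerance: treat accuracies within 1e-9 of the max as tied
  top <- grid$cv_accuracy >= max(grid$cv_accuracy) - 1e-9
  cand <- grid[top, , drop = FALSE]
  cand <- cand[order(cand$C, cand$gamma), , drop = FALSE]
  structure(list(grid = grid,
                 best_C = cand$C[1L], best_gamma = cand$gamma[1L],
                 best_accuracy = cand$cv_accuracy[1L],
                 k = as.integer(k), seed = as.integer(seed)),
            class = "lux_grid_search")
}

#' @export
print.lux_grid_search <- function(x, ...) {
  cat("<lux_grid_search>", nrow(x$grid), "cells; best C =", x$best_C,
      ", gamma =", x$best_gamma,
      sprintf(", CV accuracy = %.2f%%\n", x$best_accuracy))
  invisible(x)
}

#' Save / load an SVM model as JSON
#'
#' The JSON file is self-sufficient: kernel width, regularization,
#' support vectors, dual coefficients, bias, the feature subset and the
#' scaling parameters. `load_model(save_model(m, f))` reproduces decision
#' values to full double precision.
#'
#' @param model A `lux_svm` model.
#' @param path JSON path.
#' @param extra Optional named list of provenance fields (seed, config
#'   hash) stored alongside the model.
#' @return For the writer, `path` invisibly; for the reader, a `lux_svm`.
#' @export
save_model <- function(model, path, extra = list()) {
  stopifnot(inherits(model, "lux_svm"))
  payload <- c(list(
    format = "luxpred_svm_model",
    gamma = model$gamma, C = model$C,
    feature_ids = model$feature_ids,
    scaling = if (!is.null(model$scaling))
      list(center = as.numeric(model$scaling$center),
           scale = as.numeric(model$scaling$scale)),
    support_vectors = model$SV,  # serialized as an array of rows
    dual_coefs = model$dual_coefs,
    bias = model$bias), extra)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_format("model file not found: ", path)
  p <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                          simplifyMatrix = TRUE)
  if (!identical(p$format, "luxpred_svm_model"))
    stop_format("not a luxpred model file: ", path)
  scaling <- if (!is.null(p$scaling))
    list(center = stats::setNames(p$scaling$center, p$feature_ids),
         scale = stats::setNames(p$scaling$scale, p$feature_ids))
  SV <- p$support_vectors
  if (is.list(SV)) SV <- do.call(rbind, lapply(SV, as.numeric))
  SV <- matrix(as.numeric(SV), ncol = length(p$feature_ids))
  structure(list(gamma = p$gamma, C = p$C,
                 SV = SV,
                 dual_coefs = as.numeric(p$dual_coefs),
                 bias = p$bias,
                 feature_ids = as.character(p$feature_ids),
                 scaling = scaling),
            class = "lux_svm")
}
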