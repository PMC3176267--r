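test_that("rbf_kernel matches its closed form", {
  expect_equal(rbf_kernel(c(1, 2, 3), c(1, 2, 3), 0.7), 1.0)
  expect_equal(rbf_kernel(c(5, -2), c(0, 9), 0), 1.0)
  # ||a - b||^2 = 2  =>  exp(-0.5 * 2) = exp(-1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 1), 0.5), 0.367879441171442,
               tolerance = 1e-12)
  expect_equal(rbf_kernel(c(0, 0), c(1, 1), 0.5),
               rbf_kernel(c(1, 1), c(0, 0), 0.5))
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), 1), "dimension")
  expect_error(rbf_kernel(c(1, 2), c(1, 2), -1),
               class = "luxpred_config_error")
})

test_that("decision function evaluates a hand-built model exactly", {
  # one support vector x1 = 0, y1*alpha1 = 2, b = -1, gamma = ln 2:
  # f(0) = 2*1 - 1 = 1 -> +1;  f(1) = 2*exp(-ln 2) - 1 = 0 -> -1 (boundary)
  model <- structure(list(gamma = log(2), C = 1,
                          SV = matrix(0, 1, 1), dual_coefs = 2, bias = -1,
                          feature_ids = "f1", scaling = NULL),
                     class = "lux_svm")
  expect_equal(decision_value(model, 0), 1, tolerance = 1e-12)
  expect_equal(decision_value(model, 1), 0, tolerance = 1e-12)
  expect_identical(predict_label(model, 0), 1L)
  expect_identical(predict_label(model, 1), -1L)  # 0 maps to -1
  expect_error(decision_value(model, c(1, 2)), "dimension")
  degenerate <- model; degenerate$SV <- matrix(0, 0, 1)
  expect_error(decision_value(degenerate, 0), "support vectors")
})

test_that("trained model separates trivial and XOR data", {
  m <- tiny_labeled_matrix(matrix(c(-1, 1)), c(-1L, 1L))
  fit <- train_svm(m, C = 1000, gamma = 1)
  expect_lt(decision_value(fit, -1), 0)
  expect_gt(decision_value(fit, 1), 0)
  # classical RBF-separable XOR
  X <- matrix(c(-1, -1, 1, 1, -1, 1, 1, -1), ncol = 2, byrow = TRUE)
  y <- c(1L, 1L, -1L, -1L)
  xor_fit <- train_svm(tiny_labeled_matrix(X, y), C = 100, gamma = 1)
  expect_identical(predict_label(xor_fit, X), y)
  # duplicated separable data leaves probe-grid predictions unchanged
  m2 <- tiny_labeled_matrix(matrix(c(-2, -1.5, 1.5, 2)), c(-1L, -1L, 1L, 1L))
  dup <- tiny_labeled_matrix(matrix(rep(m2$X, 2)), rep(m2$y, 2))
  probe <- matrix(seq(-3, 3, 0.5))
  expect_identical(predict_label(train_svm(m2, 10, 0.5), probe),
                   predict_label(train_svm(dup, 10, 0.5), probe))
})

test_that("stored model invariants hold and decisions match the backbone", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, -1), ncol = 2), matrix(rnorm(40, 1), ncol = 2))
  y <- rep(c(-1L, 1L), each = 20)
  m <- tiny_labeled_matrix(X, y)
  fit <- train_svm(m, C = 2, gamma = 0.5)
  expect_true(all(abs(fit$dual_coefs) > 0))
  expect_true(all(abs(fit$dual_coefs) <= 2 + 1e-9))  # |y alpha| <= C
  expect_lte(nrow(fit$SV), nrow(X))
  # self-sufficient reconstruction agrees with the solver's own decisions
  ref <- e1071::svm(X, factor(y, levels = c(1L, -1L)), kernel = "radial",
                    cost = 2, gamma = 0.5, scale = FALSE, shrinking = FALSE)
  dv <- as.numeric(attr(predict(ref, X, decision.values = TRUE),
                        "decision.values"))
  orient <- if (identical(ref$levels[ref$labels[1]], "1")) 1 else -1
  expect_equal(decision_value(fit, X), orient * dv, tolerance = 1e-9)
  expect_error(train_svm(tiny_labeled_matrix(X, rep(1L, 40)), 1, 1),
               "both classes")
})

test_that("model JSON round-trip reproduces decision values to 1e-9", {
  set.seed(8)
  X <- rbind(matrix(rnorm(30, -1), ncol = 3), matrix(rnorm(30, 1), ncol = 3))
  m <- tiny_labeled_matrix(X, rep(c(-1L, 1L), each = 10))
  sc <- fit_standardizer(m)
  fit <- train_svm(apply_standardizer(m, sc), C = 4, gamma = 0.25,
                   scaling = sc)
  f <- tempfile(fileext = ".json")
  save_model(fit, f)
  back <- load_model(f)
  probe <- matrix(rnorm(15), ncol = 3)
  expect_equal(decision_value(back, probe), decision_value(fit, probe),
               tolerance = 1e-9)
  expect_identical(back$feature_ids, fit$feature_ids)
  expect_equal(back$scaling$center, fit$scaling$center)
  expect_error(load_model(write_tmp("{}", ".json")),
               class = "luxpred_format_error")
})

test_that("stratified k-fold partitions evenly and reproducibly", {
  y <- rep(c(1L, -1L), each = 10)
  f1 <- stratified_kfold(y, k = 5L, seed = 42L)
  f2 <- stratified_kfold(y, k = 5L, seed = 42L)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:5)
  for (fold in 1:5) {
    expect_equal(sum(f1 == fold & y == 1L), 2L)
    expect_equal(sum(f1 == fold & y == -1L), 2L)
  }
  # imbalanced: per-class counts differ by <= 1 across folds
  y2 <- rep(c(1L, -1L), c(11, 7))
  f3 <- stratified_kfold(y2, k = 3L, seed = 1L)
  counts <- table(f3, y2)
  expect_lte(max(counts[, 1]) - min(counts[, 1]), 1)
  expect_lte(max(counts[, 2]) - min(counts[, 2]), 1)
  expect_error(stratified_kfold(rep(c(1L, -1L), c(3, 12)), k = 5L),
               class = "luxpred_config_error")
})

test_that("grid search finds a perfect cell on wide-margin data and is
           order invariant", {
  set.seed(12)
  X <- rbind(matrix(rnorm(40, -6, 0.3), ncol = 2),
             matrix(rnorm(40, 6, 0.3), ncol = 2))
  m <- tiny_labeled_matrix(X, rep(c(-1L, 1L), each = 20))
  g <- grid_search_cv(m, C_grid = 2^c(-1, 3, 7), gamma_grid = 2^c(-7, -3, 1),
                      k = 5L, seed = 2L)
  expect_equal(g$best_accuracy, 100)
  expect_true(all(g$grid$cv_accuracy >= 0 & g$grid$cv_accuracy <= 100))
  # permuting the grids changes nothing (tie-break: smallest C then gamma)
  g2 <- grid_search_cv(m, C_grid = 2^c(7, -1, 3), gamma_grid = 2^c(1, -7, -3),
                       k = 5L, seed = 2L)
  expect_equal(c(g2$best_C, g2$best_gamma), c(g$best_C, g$best_gamma))
  # singleton grid
  g3 <- grid_search_cv(m, C_grid = 1, gamma_grid = 0.1, k = 5L, seed = 2L)
  expect_equal(c(g3$best_C, g3$best_gamma), c(1, 0.1))
  # each fold accuracy is reproducible => the average is too
  g4 <- grid_search_cv(m, C_grid = 1, gamma_grid = 0.1, k = 5L, seed = 2L)
  expect_equal(g3$grid$cv_accuracy, g4$grid$cv_accuracy)
})
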