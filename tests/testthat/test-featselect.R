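make_separated <- function(n_per_class = 10L, seed = 5L) {
  set.seed(seed)
  X <- cbind(c(rnorm(n_per_class, -2, 0.3), rnorm(n_per_class, 2, 0.3)),
             rep(1.5, 2L * n_per_class),
             rnorm(2L * n_per_class))
  tiny_labeled_matrix(X, rep(c(-1L, 1L), each = n_per_class))
}

test_that("ReliefF rewards a separating feature and zeroes a constant one", {
  m <- make_separated()
  r <- relieff_weights(m, k_neighbors = 3L)
  w <- setNames(r$scores, r$feature_ids)
  expect_gt(w["f1"], 0)
  expect_equal(unname(w["f2"]), 0)
  expect_gt(w["f1"], w["f3"])
  expect_identical(r$feature_ids[1L], "f1")
})

test_that("ReliefF matches an independently coded brute-force oracle", {
  set.seed(9)
  for (trial in 1:3) {
    X <- matrix(rnorm(18), nrow = 6)
    y <- rep(c(1L, -1L), 3)
    m <- tiny_labeled_matrix(X, y)
    r <- relieff_weights(m, k_neighbors = 1L)
    w <- setNames(r$scores, r$feature_ids)
    expect_equal(unname(w[paste0("f", 1:3)]), brute_relieff(X, y, 1L),
                 tolerance = 1e-12)
  }
  # unbalanced classes exercise the prior weighting
  X <- matrix(rnorm(27), nrow = 9)
  y <- rep(c(1L, -1L, -1L), 3)
  w <- with(relieff_weights(tiny_labeled_matrix(X, y), 2L),
            setNames(scores, feature_ids))
  expect_equal(unname(w[paste0("f", 1:3)]), brute_relieff(X, y, 2L),
               tolerance = 1e-12)
})

test_that("ReliefF is invariant to row order and instance duplication", {
  m <- make_separated(8L, seed = 13L)
  r1 <- relieff_weights(m, 3L)
  perm <- sample(nrow(m$X))
  r2 <- relieff_weights(tiny_labeled_matrix(m$X[perm, ], m$y[perm]), 3L)
  expect_equal(setNames(r1$scores, r1$feature_ids),
               setNames(r2$scores, r2$feature_ids))
  dup <- tiny_labeled_matrix(rbind(m$X, m$X), c(m$y, m$y))
  r3 <- relieff_weights(dup, 3L)
  expect_identical(r3$feature_ids, r1$feature_ids)
})

test_that("ReliefF rejects degenerate inputs", {
  m <- make_separated()
  expect_error(relieff_weights(tiny_labeled_matrix(m$X, rep(1L, 20))),
               "both classes")
  expect_error(relieff_weights(m, k_neighbors = 10L), "smaller class",
               class = "luxpred_config_error")
})

test_that("information gain reproduces hand-computed entropy arithmetic", {
  # perfect predictor of a balanced binary class: 1 bit
  m <- tiny_labeled_matrix(cbind(rep(c(0, 1), each = 4)),
                           rep(c(-1L, 1L), each = 4))
  expect_equal(infogain_scores(m)$scores, 1.0)
  # identical value multisets in both classes: no information
  m0 <- tiny_labeled_matrix(cbind(rep(1:4, 2)), rep(c(-1L, 1L), each = 4))
  expect_equal(infogain_scores(m0)$scores, 0)
  # 8 instances, one candidate cut (between 5 and 6), unbalanced 5/3 split:
  # score = H(5/8, 3/8) - 0 = 0.954434002924965 by direct entropy arithmetic
  m1 <- tiny_labeled_matrix(cbind(1:8), c(rep(-1L, 5), rep(1L, 3)))
  expect_equal(infogain_scores(m1)$scores, 0.954434002924965,
               tolerance = 1e-12)
})

test_that("MDL criterion refuses to split class-independent features", {
  set.seed(21)
  X <- cbind(rnorm(40), rnorm(40, 0, 5))
  y <- rep(c(1L, -1L), 20)  # labels independent of X
  sc <- infogain_scores(tiny_labeled_matrix(X, y))$scores
  expect_equal(sc, c(0, 0))
})

test_that("infogain ranking is row-order invariant", {
  m <- make_separated(10L, seed = 31L)
  r1 <- infogain_scores(m)
  perm <- sample(nrow(m$X))
  r2 <- infogain_scores(tiny_labeled_matrix(m$X[perm, ], m$y[perm]))
  expect_identical(r1$feature_ids, r2$feature_ids)
  expect_equal(r1$scores, r2$scores)
})

test_that("mRMR matches a brute-force greedy loop over tabulated MI", {
  set.seed(17)
  for (trial in 1:3) {
    X <- matrix(rnorm(100), nrow = 20)
    y <- rep(c(1L, -1L), 10)
    X[, 2] <- y + rnorm(20, 0, 0.4)      # relevant feature
    X[, 4] <- X[, 2] + rnorm(20, 0, 0.1) # redundant with it
    m <- tiny_labeled_matrix(X, y)
    r <- mrmr_order(m, 3L)
    expect_identical(r$feature_ids,
                     paste0("f", brute_mrmr(X, y, 3L)))
  }
})

test_that("mRMR first pick maximizes relevance; full selection permutes", {
  set.seed(23)
  X <- matrix(rnorm(60), nrow = 12)
  y <- rep(c(1L, -1L), 6)
  X[, 3] <- 2 * y + rnorm(12, 0, 0.2)
  m <- tiny_labeled_matrix(X, y)
  # first step is by definition the argmax of I(f; class), here tabulated
  # by the brute-force oracle
  expect_identical(mrmr_order(m, 1L)$feature_ids,
                   paste0("f", brute_mrmr(X, y, 1L)))
  full <- mrmr_order(m, 5L)
  expect_setequal(full$feature_ids, paste0("f", 1:5))
  expect_error(mrmr_order(m, 6L), class = "luxpred_config_error")
})

test_that("relevance scores are nonnegative and bounded by class entropy", {
  set.seed(29)
  X <- matrix(rnorm(80), nrow = 16)
  y <- rep(c(1L, -1L), 8)
  ig <- infogain_scores(tiny_labeled_matrix(X, y))
  expect_true(all(ig$scores >= 0))
  expect_true(all(ig$scores <= 1 + 1e-12))  # H(class) = 1 bit, balanced
  first_rel <- mrmr_order(tiny_labeled_matrix(X, y), 1L)$scores
  expect_gte(first_rel, 0)
  expect_lte(first_rel, 1 + 1e-12)
})

test_that("top_k respects order, bounds and the index tie-break", {
  r <- feature_ranking("relieff", paste0("f", c(2, 5, 1)), c(3, 2, 1))
  expect_identical(top_k(r, 3L), c("f2", "f5", "f1"))
  expect_identical(top_k(r, 1L), "f2")
  expect_error(top_k(r, 0L), class = "luxpred_config_error")
  expect_error(top_k(r, 4L), class = "luxpred_config_error")
  # equal scores: ascending original feature index wins
  m <- tiny_labeled_matrix(cbind(rep(c(0, 1), each = 4),
                                 rep(c(0, 1), each = 4)),
                           rep(c(-1L, 1L), each = 4))
  expect_identical(infogain_scores(m)$feature_ids, c("f1", "f2"))
})
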