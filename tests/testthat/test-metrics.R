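test_that("confusion counts tally by definition", {
  c1 <- confusion_counts(c(1, -1), c(1, -1))
  expect_equal(unclass(c1)[c("TP", "TN", "FP", "FN")],
               list(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  c2 <- confusion_counts(c(1, -1), c(-1, 1))
  expect_equal(c2$FP, 1L); expect_equal(c2$FN, 1L)
  # n = 6 mixed case tallied by hand
  yt <- c(1, 1, 1, -1, -1, -1)
  yp <- c(1, -1, 1, -1, 1, -1)
  c3 <- confusion_counts(yt, yp)
  expect_equal(unclass(c3)[c("TP", "FP", "TN", "FN")],
               list(TP = 2L, FP = 1L, TN = 2L, FN = 1L))
  expect_equal(c3$TP + c3$FP + c3$TN + c3$FN, 6L)
  expect_error(confusion_counts(c(1, 0), c(1, 1)),
               class = "luxpred_format_error")
  expect_error(confusion_counts(c(1, -1), c(1, -1, 1)), "equal length")
})

test_that("metrics reproduce the reconstructed benchmark-table row", {
  # 141 positives, 190 negatives: TP = 105, FP = 30, TN = 160, FN = 36
  m <- classification_metrics(list(TP = 105, FP = 30, TN = 160, FN = 36))
  expect_equal(round(m$sensitivity, 2), 74.47)
  expect_equal(round(m$specificity, 2), 84.21)
  expect_equal(round(m$accuracy, 2), 80.06)
  expect_equal(round(m$mcc, 4), 0.5904)
})

test_that("MCC hits its extremes and the zero-denominator convention", {
  expect_equal(classification_metrics(list(TP = 7, FP = 0, TN = 5, FN = 0))$mcc, 1)
  expect_equal(classification_metrics(list(TP = 0, FP = 4, TN = 0, FN = 6))$mcc, -1)
  expect_warning(
    m0 <- classification_metrics(list(TP = 0, FP = 0, TN = 5, FN = 5)),
    "MCC")
  expect_equal(m0$mcc, 0)
  expect_true(m0$mcc_undefined)
  expect_error(classification_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "no observations")
})

test_that("metric identities hold across random confusion tables", {
  set.seed(4)
  for (i in 1:25) {
    counts <- list(TP = rpois(1, 20) + 1, FP = rpois(1, 10) + 1,
                   TN = rpois(1, 20) + 1, FN = rpois(1, 10) + 1)
    m <- classification_metrics(counts)
    P <- counts$TP + counts$FN; N <- counts$TN + counts$FP
    expect_equal(m$accuracy,
                 (m$sensitivity * P + m$specificity * N) / (P + N))
    swapped <- classification_metrics(list(TP = counts$TN, FP = counts$FN,
                                           TN = counts$TP, FN = counts$FP))
    expect_equal(swapped$mcc, m$mcc)
    expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
  }
})

test_that("ROC endpoints, perfect ranking and tie conventions", {
  scores <- c(0.9, 0.8, 0.2, 0.1)
  y <- c(1L, 1L, -1L, -1L)
  pts <- roc_points(scores, y)
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_equal(roc_auc(pts), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), rep(c(1L, -1L), 3)), 0.5)
  expect_error(roc_points(1:3, rep(1L, 3)), "both classes")
})

test_that("AUC equals brute-force pair counting, with and without ties", {
  # 3+3 scores with one inversion (0.3 < 0.4)
  scores <- c(0.9, 0.7, 0.3, 0.4, 0.2, 0.1)
  y <- c(1L, 1L, 1L, -1L, -1L, -1L)
  expect_equal(roc_auc(scores, y), brute_auc(scores, y))
  expect_equal(brute_auc(scores, y), (8 + 0) / 9)
  set.seed(6)
  for (i in 1:10) {
    s <- round(rnorm(14), 1)  # rounding induces ties
    yy <- rep(c(1L, -1L), 7)
    expect_equal(roc_auc(s, yy), brute_auc(s, yy), tolerance = 1e-12)
    expect_equal(roc_auc(-s, yy), 1 - roc_auc(s, yy), tolerance = 1e-12)
  }
})

test_that("pROC agrees with the trapezoid AUC as an independent check", {
  set.seed(10)
  s <- rnorm(30)
  y <- rep(c(1L, -1L), 15)
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        levels = c(-1, 1),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
})
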