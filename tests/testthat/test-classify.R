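classifiers <- c("mahalanobis", "lda", "qda", "svm_linear")

test_that("all four classifiers separate a wide-margin 1-D problem perfectly", {
  x <- c(seq(0, 0.4, 0.1), seq(10, 10.4, 0.1))
  y <- rep(c("before", "after"), each = 5)
  for (cl in classifiers) {
    expect_identical(loocv_predict(x, y, cl), y,
                     info = cl)
  }
  rep_all <- classifier_report(x, y)
  expect_true(all(rep_all$F1 == 100))
  expect_equal(attr(rep_all, "OA"), 100)
})

test_that("label permutation brings mean F1 to the chance band", {
  set.seed(10)
  x <- rnorm(12)
  y <- rep(c("before", "after"), each = 6)
  f1 <- replicate(100, {
    yp <- sample(y)
    mean(vapply(c("lda", "mahalanobis"), function(cl) {
      confusion_metrics(loocv_predict(x, yp, cl), yp)$F1
    }, 0))
  })
  expect_gt(mean(f1), 40)
  expect_lt(mean(f1), 60)
})

test_that("duplicating every recording leaves Gaussian classifiers unchanged", {
  set.seed(11)
  x <- matrix(rnorm(40), 20, 2)
  x[11:20, ] <- x[11:20, ] + 3
  y <- rep(c("before", "after"), each = 10)
  for (cl in c("lda", "qda", "mahalanobis")) {
    p1 <- loocv_predict(x, y, cl)
    p2 <- loocv_predict(rbind(x, x), c(y, y), cl)
    # held-out predictions for the original rows are preserved
    expect_identical(p2[seq_len(20)], p1, info = cl)
  }
  # the SVM decision is invariant to duplicating both classes equally
  p1 <- loocv_predict(x, y, "svm_linear")
  p2 <- loocv_predict(rbind(x, x), c(y, y), "svm_linear")
  expect_identical(p2[seq_len(20)], p1)
})

test_that("LDA coincides with pooled-covariance Mahalanobis at equal priors", {
  set.seed(12)
  xtr <- matrix(rnorm(60), 30, 2)
  xtr[16:30, ] <- xtr[16:30, ] + 1
  ytr <- factor(rep(c("before", "after"), each = 15),
                levels = c("before", "after"))
  xte <- matrix(rnorm(40), 20, 2)
  fit <- MASS::lda(xtr, grouping = ytr, prior = c(0.5, 0.5))
  p_lda <- as.character(stats::predict(fit, xte)$class)
  p_mah <- ppgheat:::mahalanobis_classify(xtr, ytr, xte, covariance = "pooled")
  expect_identical(p_mah, p_lda)
})

test_that("confusion metrics implement the SE/PP/F1 definitions", {
  truth <- rep(c("after", "before"), c(40, 40))
  perfect <- confusion_metrics(truth, truth)
  expect_equal(unlist(perfect[, c("SE", "PP", "F1")]),
               c(SE = 100, PP = 100, F1 = 100))

  # SE = PP = 80 -> F1 = 80 (harmonic mean of equal values)
  pred <- truth
  pred[1:8] <- "before"   # 8 of 40 positives missed
  pred[41:48] <- "after"  # 8 false alarms
  m <- confusion_metrics(pred, truth)
  expect_equal(unlist(m[, c("SE", "PP", "F1")]), c(SE = 80, PP = 80, F1 = 80))

  # degenerate prediction: no positives predicted -> flagged zero F1
  m0 <- confusion_metrics(rep("before", 80), truth)
  expect_equal(m0$F1, 0)
  expect_true(m0$f1_undefined)

  expect_error(confusion_metrics(c("yes", "no"), c("after", "before")),
               "unknown label")
})

test_that("overall accuracy is the mean of the F1 scores", {
  expect_equal(overall_accuracy(c(80, 80, 80, 80)), 80)
  expect_equal(overall_accuracy(c(100, 0, 100, 0)), 50)
  f1 <- c(77.4, 80.1, 79.5, 83.3)
  expect_equal(overall_accuracy(f1), mean(f1))
  # invariant to classifier ordering
  expect_equal(overall_accuracy(rev(f1)), overall_accuracy(f1))
})

test_that("leave-one-subject-out holds out both recordings of a subject", {
  # each subject's two recordings are identical; recording-wise LOOCV can
  # learn from the twin, subject-wise LOOCV cannot
  set.seed(13)
  base <- rnorm(8)
  x <- c(base, base + 10)
  x <- rep(x, each = 2)
  y <- rep(rep(c("before", "after"), each = 8), each = 2)
  groups <- rep(seq_len(16), each = 2)
  p_grouped <- loocv_predict(x, y, "lda", groups = groups)
  expect_identical(p_grouped, y) # wide margin: grouping must not hurt
  # grouped folds never see the held-out subject: a lone outlier subject
  # with a flipped label is misclassified under grouping
  x2 <- c(rep(0, 6), 20, 20, rep(10, 6))
  y2 <- rep(c("before", "after"), c(8, 6))
  g2 <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7)
  p2 <- loocv_predict(x2, y2, "lda", groups = g2)
  expect_identical(p2[7:8], c("after", "after"))
})

test_that("degenerate training folds fall back to a regularized rule", {
  # zero within-class variance in one dimension
  x <- cbind(c(rep(0, 6), rep(1, 6)), rep(1, 12))
  y <- rep(c("before", "after"), each = 6)
  for (cl in classifiers) {
    pred <- loocv_predict(x, y, cl)
    expect_identical(pred, y, info = cl)
  }
  expect_error(loocv_predict(1:4, rep(c("before", "after"), 2)), "3 recordings")
})
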