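# Leave-one-out benchmarking of four classifiers: Mahalanobis distance,
# LDA, QDA and the linear SVM. Labels are "before" (rest, the negative
# class) and "after" (heat stress, the positive class). Priors are equal
# (balanced design); ties in the Mahalanobis rule fall to "before" for
# reproducibility.

CLASSIFIERS <- c("mahalanobis", "lda", "qda", "svm_linear")

as_label_factor <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), c("before", "after"))
  if (length(bad)) {
    stop("unknown label value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(y, levels = c("before", "after"))
}

ridge_cov <- function(x) {
  s <- stats::cov(x)
  ok <- tryCatch({ chol(s); TRUE }, error = function(e) FALSE)
  if (!ok || !all(is.finite(s))) {
    s[!is.finite(s)] <- 0
    tr <- sum(diag(s))
    if (tr <= 0) tr <- 1
    s <- s + diag(1e-6 * tr / ncol(x), ncol(x))
  }
  s
}

# Nearest-class-in-Mahalanobis-distance rule; covariance per class by
# default, pooled optionally (in which case it coincides with equal-prior
# LDA). Degenerate covariances get a trace-scaled ridge.
mahalanobis_classify <- function(xtr, ytr, xte,
                                 covariance = c("class", "pooled")) {
  covariance <- match.arg(covariance)
  mu_b <- colMeans(xtr[ytr == "before", , drop = FALSE])
  mu_a <- colMeans(xtr[ytr == "after", , drop = FALSE])
  if (covariance == "pooled") {
    xb <- sweep(xtr[ytr == "before", , drop = FALSE], 2, mu_b)
    xa <- sweep(xtr[ytr == "after", , drop = FALSE], 2, mu_a)
    sp <- ridge_cov(rbind(xb, xa))
    d_b <- stats::mahalanobis(xte, mu_b, sp)
    d_a <- stats::mahalanobis(xte, mu_a, sp)
  } else {
    d_b <- stats::mahalanobis(xte, mu_b, ridge_cov(xtr[ytr == "before", , drop = FALSE]))
    d_a <- stats::mahalanobis(xte, mu_a, ridge_cov(xtr[ytr == "after", , drop = FALSE]))
  }
  ifelse(d_a < d_b, "after", "before")
}

# Regularized Gaussian discriminant used when MASS::lda/qda cannot fit
# (e.g. zero within-class variance in a fold).
gaussian_fallback <- function(xtr, ytr, xte, quadratic) {
  if (!quadratic) return(mahalanobis_classify(xtr, ytr, xte, "pooled"))
  score <- function(cls) {
    xc <- xtr[ytr == cls, , drop = FALSE]
    s <- ridge_cov(xc)
    -0.5 * stats::mahalanobis(xte, colMeans(xc), s) -
      0.5 * determinant(s, logarithm = TRUE)$modulus
  }
  ifelse(score("after") > score("before"), "after", "before")
}

predict_fold <- function(classifier, xtr, ytr, xte) {
  # columns constant across the training fold carry no discriminant
  # information and break covariance-based rules; drop them up front
  keep <- apply(xtr, 2, function(v) stats::sd(v) > 0)
  if (!any(keep)) return(rep("before", nrow(xte)))
  xtr <- xtr[, keep, drop = FALSE]
  xte <- xte[, keep, drop = FALSE]
  switch(classifier,
    mahalanobis = mahalanobis_classify(xtr, ytr, xte),
    lda = tryCatch({
      fit <- MASS::lda(xtr, grouping = ytr, prior = c(0.5, 0.5))
      as.character(stats::predict(fit, xte)$class)
    }, error = function(e) gaussian_fallback(xtr, ytr, xte, FALSE)),
    qda = tryCatch({
      fit <- MASS::qda(xtr, grouping = ytr, prior = c(0.5, 0.5))
      as.character(stats::predict(fit, xte)$class)
    }, error = function(e) gaussian_fallback(xtr, ytr, xte, TRUE)),
    svm_linear = {
      ctr <- colMeans(xtr)
      scl <- apply(xtr, 2, stats::sd)
      scl[scl == 0 | !is.finite(scl)] <- 1
      xs <- scale(xtr, ctr, scl)
      ts <- scale(xte, ctr, scl)
      fit <- e1071::svm(xs, ytr, kernel = "linear", cost = 1, scale = FALSE,
                        type = "C-classification")
      as.character(stats::predict(fit, ts))
    },
    stop("unknown classifier: ", classifier, call. = FALSE)
  )
}

#' Leave-one-out cross-validated predictions
#'
#' One fold per recording: the classifier is refit on all remaining
#' recordings and predicts the held-out one. Per-fold standardization for
#' the SVM uses training-fold statistics only.
#'
#' @param x Feature matrix (rows = recordings) or vector for a single
#'   feature.
#' @param y Labels, `"before"` / `"after"`; both classes must appear with at
#'   least 3 recordings each.
#' @param classifier One of `"mahalanobis"`, `"lda"`, `"qda"`,
#'   `"svm_linear"`.
#' @param groups Optional grouping vector (e.g. subject IDs): each fold
#'   holds out every recording sharing the held-out row's group
#'   (leave-one-subject-out). Default `NULL` leaves out single recordings.
#'
#' @return Character vector of held-out predictions, one per row of `x`.
#' @export
loocv_predict <- function(x, y, classifier = CLASSIFIERS, groups = NULL) {
  classifier <- match.arg(classifier)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as_label_factor(y)
  if (nrow(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (min(table(y)) < 3L) {
    stop("need at least 3 recordings per class", call. = FALSE)
  }
  n <- nrow(x)
  if (!is.null(groups) && length(groups) != n) {
    stop("'groups' must match the number of recordings", call. = FALSE)
  }
  pred <- character(n)
  for (i in seq_len(n)) {
    out <- if (is.null(groups)) i else which(groups == groups[i])
    pred[i] <- predict_fold(classifier, x[-out, , drop = FALSE], y[-out],
                            x[i, , drop = FALSE])
  }
  pred
}

#' Confusion counts and SE/PP/F1 for one classifier
#'
#' Sensitivity `SE = 100 TP / (TP + FN)`, positive predictivity
#' `PP = 100 TP / (TP + FP)` and `F1 = 2 SE PP / (SE + PP)`, with heat
#' stress (`"after"`) as the positive class. An undefined F1 (SE + PP = 0)
#' is reported as 0 with `f1_undefined = TRUE`.
#'
#' @param pred,truth Label vectors of equal length.
#' @param positive Positive class (default `"after"`).
#'
#' @return One-row data frame: `TP`, `FN`, `FP`, `TN`, `SE`, `PP`, `F1`
#'   (percent), `f1_undefined`.
#' @examples
#' confusion_metrics(rep("after", 60), rep(c("after", "before"), c(35, 25)))
#' @export
confusion_metrics <- function(pred, truth, positive = "after") {
  pred <- as_label_factor(pred)
  truth <- as_label_factor(truth)
  if (length(pred) != length(truth)) {
    stop("'pred' and 'truth' lengths differ", call. = FALSE)
  }
  tp <- sum(pred == positive & truth == positive)
  fn <- sum(pred != positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  tn <- sum(pred != positive & truth != positive)
  se <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  pp <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  undefined <- isTRUE(se + pp == 0) || is.na(se)
  f1 <- if (!is.na(se) && se + pp > 0) 2 * se * pp / (se + pp) else 0
  data.frame(TP = tp, FN = fn, FP = fp, TN = tn, SE = se, PP = pp, F1 = f1,
             f1_undefined = undefined)
}

#' Overall accuracy: mean F1 across classifiers
#'
#' @param reports A `ppg_classifier_report` or data frame with an `F1`
#'   column (one row per classifier), or a numeric vector of F1 scores.
#' @return Mean F1 in percent.
#' @export
overall_accuracy <- function(reports) {
  f1 <- if (is.data.frame(reports)) reports$F1 else as.numeric(reports)
  if (length(f1) < 1L) stop("no F1 scores supplied", call. = FALSE)
  mean(f1)
}

#' Benchmark all four classifiers on one labelled feature set
#'
#' Runs leave-one-out cross-validation for each classifier and summarizes
#' confusion counts, SE, PP and F1, plus the overall accuracy (mean F1).
#'
#' @inheritParams loocv_predict
#' @param classifiers Subset of the four classifiers to run.
#'
#' @return Data frame of class `ppg_classifier_report`, one row per
#'   classifier, with attribute `OA` (also via [overall_accuracy()]).
#' @export
classifier_report <- function(x, y, classifiers = CLASSIFIERS, groups = NULL) {
  rows <- lapply(classifiers, function(cl) {
    pred <- loocv_predict(x, y, cl, groups = groups)
    cbind(classifier = cl, confusion_metrics(pred, y))
  })
  res <- do.call(rbind, rows)
  attr(res, "OA") <- overall_accuracy(res)
  class(res) <- c("ppg_classifier_report", class(res))
  res
}

#' @export
print.ppg_classifier_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$SE <- round(df$SE, 2); df$PP <- round(df$PP, 2); df$F1 <- round(df$F1, 2)
  print(df[, c("classifier", "TP", "FN", "FP", "TN", "SE", "PP", "F1")])
  cat(sprintf("Overall accuracy (mean F1): %.2f%%\n", attr(x, "OA")))
  invisible(x)
}
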