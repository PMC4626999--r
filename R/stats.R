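# Nonparametric screening: two-sided Wilcoxon-Mann-Whitney per feature cell
# and comparison, with Holm-Bonferroni family-wise correction.

#' Two-sided Wilcoxon-Mann-Whitney p-value
#'
#' For small samples (combined n <= `exact_max`) the p-value is computed by
#' exact enumeration of all group assignments of the (tied-rank) data, as
#' twice the smaller tail probability of the rank sum, capped at 1 — this
#' remains valid under ties. Larger samples use the tie-corrected normal
#' approximation with continuity correction (via [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples (each non-empty, finite).
#' @param exact_max Combined sample size up to which exact enumeration is
#'   used (default 12).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) enumeration; `NULL`
#'   (default) switches on `exact_max`.
#'
#' @return Two-sided p-value in (0, 1].
#' @examples
#' mann_whitney_p(c(1, 2), c(3, 4)) # 1/3 by enumeration
#' @export
mann_whitney_p <- function(x, y, exact_max = 12, exact = NULL) {
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(c(x, y)))) stop("samples must be finite", call. = FALSE)
  n <- length(x)
  N <- n + length(y)
  use_exact <- if (is.null(exact)) N <= exact_max else exact
  if (use_exact) {
    r <- rank(c(x, y))
    w_obs <- sum(r[seq_len(n)])
    combos <- utils::combn(N, n)
    W <- colSums(matrix(r[combos], nrow = n))
    eps <- 1e-9
    p_lo <- mean(W <= w_obs + eps)
    p_hi <- mean(W >= w_obs - eps)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  if (length(unique(c(x, y))) == 1L) return(1) # no rank separation at all
  suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  )
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the p-values ascending and compares the k-th smallest against
#' `alpha / (m - k + 1)`; rejections form a prefix of the sorted order.
#' Adjusted p-values follow the standard running-maximum definition
#' (equivalent to `stats::p.adjust(method = "holm")`, which is used
#' internally). Uniformly more powerful than plain Bonferroni.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param alpha Family-wise error level (default 0.05).
#'
#' @return List with `adjusted` (adjusted p-values, input order) and
#'   `reject` (logical flags at level `alpha`).
#' @examples
#' holm_bonferroni(c(0.01, 0.04))$reject # both TRUE at alpha = 0.05
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  adj <- stats::p.adjust(pvals, method = "holm")
  list(adjusted = adj, reject = adj <= alpha)
}

#' Mass-univariate screening of the feature table
#'
#' For every (feature, status, order) cell, compares rest (`BE`) values with
#' each available stress stage by the two-sided Mann-Whitney test, averages
#' the per-stage p-values, and applies Holm-Bonferroni across the whole
#' family of tests. The lowest mean p-value within each feature-by-status
#' block is flagged.
#'
#' @param features A `ppg_features` long-format table (see
#'   [cohort_features()]).
#' @param alpha Family-wise error level.
#' @param family `"all"` corrects across every computed test;
#'   `"orders_1_20"` restricts the correction family to derivative orders
#'   1-20 (240 tests with three stages), leaving order-0 rows uncorrected
#'   (`NA` flags).
#' @param paired Use the paired Wilcoxon signed-rank test instead of the
#'   unpaired Mann-Whitney (subjects matched by ID).
#'
#' @return Data frame of class `ppg_screening`: one row per cell with
#'   columns `feature`, `status`, `order`, `p1`..`p<k>`, `p_mean`,
#'   `holm_p1`.., `reject1`.., `block_min_pmean`.
#' @export
screen_features <- function(features, alpha = 0.05,
                            family = c("all", "orders_1_20"),
                            paired = FALSE) {
  family <- match.arg(family)
  stopifnot(is.data.frame(features))
  stages <- sort(setdiff(unique(features$condition), "BE"))
  if (!"BE" %in% features$condition || length(stages) < 1L) {
    stop("feature table must contain BE and at least one stress stage",
         call. = FALSE)
  }
  cells <- unique(features[, c("feature", "status", "order")])
  cells <- cells[order(cells$feature, cells$status, cells$order), ]
  pmat <- matrix(NA_real_, nrow(cells), length(stages))
  for (i in seq_len(nrow(cells))) {
    sub <- features[features$feature == cells$feature[i] &
                      features$status == cells$status[i] &
                      features$order == cells$order[i], ]
    be <- sub[sub$condition == "BE", ]
    for (k in seq_along(stages)) {
      ek <- sub[sub$condition == stages[k], ]
      if (nrow(be) < 2 || nrow(ek) < 2) {
        stop(sprintf("condition %s needs >= 2 subjects", stages[k]),
             call. = FALSE)
      }
      if (paired) {
        m <- merge(be[, c("subject_id", "value")],
                   ek[, c("subject_id", "value")], by = "subject_id")
        pmat[i, k] <- stats::wilcox.test(m$value.x, m$value.y,
                                         paired = TRUE, exact = FALSE)$p.value
      } else {
        pmat[i, k] <- mann_whitney_p(be$value, ek$value)
      }
    }
  }
  res <- cells
  rownames(res) <- NULL
  for (k in seq_along(stages)) res[[paste0("p", k)]] <- pmat[, k]
  res$p_mean <- rowMeans(pmat)
  in_family <- if (family == "all") rep(TRUE, nrow(res)) else res$order >= 1
  flat <- as.vector(pmat[in_family, , drop = FALSE])
  hb <- holm_bonferroni(pmin(flat, 1), alpha = alpha)
  adj <- matrix(NA_real_, nrow(res), length(stages))
  rej <- matrix(NA, nrow(res), length(stages))
  adj[in_family, ] <- matrix(hb$adjusted, sum(in_family), length(stages))
  rej[in_family, ] <- matrix(hb$reject, sum(in_family), length(stages))
  for (k in seq_along(stages)) {
    res[[paste0("holm_p", k)]] <- adj[, k]
    res[[paste0("reject", k)]] <- rej[, k]
  }
  res$block_min_pmean <- FALSE
  for (f in unique(res$feature)) for (s in unique(res$status)) {
    idx <- which(res$feature == f & res$status == s)
    res$block_min_pmean[idx[which.min(res$p_mean[idx])]] <- TRUE
  }
  attr(res, "stages") <- stages
  attr(res, "alpha") <- alpha
  attr(res, "family") <- family
  class(res) <- c("ppg_screening", class(res))
  res
}

#' Write a screening result as a wide CSV
#'
#' Rows are derivative orders; column blocks are feature-by-status cells
#' with per-stage p-values, the mean p-value, and significance flags
#' (`sig05`, `sig005`, `holm` columns mirror the conventional `*`, `**`,
#' dagger markers).
#'
#' @param screening A `ppg_screening` result.
#' @param file Path to a CSV file.
#' @export
write_screening <- function(screening, file) {
  stages <- attr(screening, "stages")
  orders <- sort(unique(screening$order))
  out <- data.frame(order = orders)
  for (f in unique(screening$feature)) for (s in unique(screening$status)) {
    sub <- screening[screening$feature == f & screening$status == s, ]
    sub <- sub[match(orders, sub$order), ]
    base <- paste(f, s, sep = "_")
    for (k in seq_along(stages)) {
      out[[paste0(base, "_p", k)]] <- sub[[paste0("p", k)]]
      out[[paste0(base, "_sig05_", k)]] <- sub[[paste0("p", k)]] <= 0.05
      out[[paste0(base, "_sig005_", k)]] <- sub[[paste0("p", k)]] <= 0.005
      out[[paste0(base, "_holm_", k)]] <- sub[[paste0("reject", k)]]
    }
    out[[paste0(base, "_pmean")]] <- sub$p_mean
  }
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
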