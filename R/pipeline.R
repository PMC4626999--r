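# Desk-scale orchestration of the full analysis: feature extraction over
# every derivative order, nonparametric screening, the classifier OA grid
# over (feature, status, order), selection of the optimal cell, and the
# combined entropy + RMSSD quadratic detector.

#' Derivative-order scan: screening and classifier grid
#'
#' Computes all energy/entropy cells for every recording, screens each cell
#' with Mann-Whitney tests (Holm-corrected), and benchmarks the four
#' classifiers under leave-one-out cross-validation on every
#' (feature, status, order) cell for each rest-vs-stage comparison. The
#' overall accuracy (mean F1 across classifiers) fills the OA grid; the
#' argmax-OA cell per feature-by-status block and overall is reported.
#'
#' @param cohort A `ppg_cohort`.
#' @param spec [filter_spec()] for the filtered branch.
#' @param max_order Cascade depth (default 20).
#' @param alpha Screening family-wise level.
#' @param classifiers Classifiers to benchmark (default all four).
#' @param family Holm correction family, see [screen_features()].
#'
#' @return Object of class `ppg_scan`: list with `features`, `screening`,
#'   `oa_grid` (per cell x comparison), `oa_cells` (per cell, mean across
#'   comparisons), `optimal` (per-block and overall argmax), `config`.
#' @export
run_scan <- function(cohort, spec = filter_spec(), max_order = 20,
                     alpha = 0.05, classifiers = CLASSIFIERS,
                     family = "all") {
  stopifnot(inherits(cohort, "ppg_cohort"))
  features <- cohort_features(cohort, spec, max_order = max_order)
  screening <- screen_features(features, alpha = alpha, family = family)
  stages <- attr(screening, "stages")
  cells <- unique(features[, c("feature", "status", "order")])
  cells <- cells[order(cells$feature, cells$status, cells$order), ]
  rownames(cells) <- NULL
  grid <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- features[features$feature == cells$feature[i] &
                      features$status == cells$status[i] &
                      features$order == cells$order[i], ]
    be <- sub[sub$condition == "BE", ]
    for (st in stages) {
      ek <- sub[sub$condition == st, ]
      x <- c(be$value, ek$value)
      y <- rep(c("before", "after"), c(nrow(be), nrow(ek)))
      rep_i <- tryCatch(
        classifier_report(x, y, classifiers = classifiers),
        error = function(e) {
          stop(sprintf("classification failed for (%s, %s, order %d, BE vs %s): %s",
                       cells$feature[i], cells$status[i], cells$order[i],
                       st, conditionMessage(e)), call. = FALSE)
        })
      grid[[length(grid) + 1L]] <- data.frame(
        feature = cells$feature[i], status = cells$status[i],
        order = cells$order[i], comparison = paste0("BE_vs_", st),
        OA = attr(rep_i, "OA")
      )
    }
  }
  oa_grid <- do.call(rbind, grid)
  oa_cells <- stats::aggregate(OA ~ feature + status + order, oa_grid, mean)
  oa_cells <- oa_cells[order(oa_cells$feature, oa_cells$status, oa_cells$order), ]
  rownames(oa_cells) <- NULL
  blocks <- unique(oa_cells[, c("feature", "status")])
  opt_rows <- lapply(seq_len(nrow(blocks)), function(b) {
    sub <- oa_cells[oa_cells$feature == blocks$feature[b] &
                      oa_cells$status == blocks$status[b], ]
    sub[which.max(sub$OA), ]
  })
  optimal_blocks <- do.call(rbind, opt_rows)
  rownames(optimal_blocks) <- NULL
  optimal <- oa_cells[which.max(oa_cells$OA), ]
  structure(list(features = features, screening = screening,
                 oa_grid = oa_grid, oa_cells = oa_cells,
                 optimal_blocks = optimal_blocks, optimal = optimal,
                 config = list(spec = spec, max_order = max_order,
                               alpha = alpha, classifiers = classifiers,
                               family = family, stages = stages)),
            class = "ppg_scan")
}

#' @export
print.ppg_scan <- function(x, ...) {
  cat(sprintf("<ppg_scan> %d cells x %d comparisons, classifiers: %s\n",
              nrow(x$oa_cells), length(x$config$stages),
              paste(x$config$classifiers, collapse = ", ")))
  cat("Optimal cell per feature/status block (mean OA across comparisons):\n")
  ob <- x$optimal_blocks
  ob$OA <- round(ob$OA, 1)
  print(ob)
  cat(sprintf("Overall optimal: %s / %s, order %d (OA %.1f%%)\n",
              x$optimal$feature, x$optimal$status, x$optimal$order,
              x$optimal$OA))
  invisible(x)
}

#' @export
summary.ppg_scan <- function(object, ...) {
  scr <- object$screening
  n_rej <- sum(unlist(scr[grep("^reject", names(scr))]), na.rm = TRUE)
  cat(sprintf("Screening: %d cells, %d Holm-significant tests at alpha = %g\n",
              nrow(scr), n_rej, attr(scr, "alpha")))
  best <- scr[scr$block_min_pmean, c("feature", "status", "order", "p_mean")]
  cat("Lowest mean p-value per block:\n")
  print(best, row.names = FALSE)
  print(object)
  invisible(object)
}

#' @export
plot.ppg_scan <- function(x, ...) {
  blocks <- unique(x$oa_cells[, c("feature", "status")])
  cols <- c("black", "red3", "blue3", "darkgreen")
  graphics::plot(NULL, xlim = range(x$oa_cells$order),
                 ylim = range(x$oa_cells$OA), xlab = "derivative order",
                 ylab = "overall accuracy (%)",
                 main = "Classifier OA by derivative order", ...)
  for (b in seq_len(nrow(blocks))) {
    sub <- x$oa_cells[x$oa_cells$feature == blocks$feature[b] &
                        x$oa_cells$status == blocks$status[b], ]
    graphics::lines(sub$order, sub$OA, col = cols[b], lwd = 2)
  }
  graphics::legend("bottomright", bty = "n", lwd = 2, col = cols[seq_len(nrow(blocks))],
                   legend = paste(blocks$feature, blocks$status, sep = "/"))
  invisible(x)
}

#' Combined entropy + RMSSD quadratic detector
#'
#' Pairs a single derivative feature (by default the entropy of the
#' seventh derivative of the filtered signal) with the RMSSD of each
#' recording and evaluates QDA under leave-one-out cross-validation for each
#' rest-vs-stage comparison. Recordings without a computable RMSSD (fewer
#' than three detected beats) are excluded; more than `max_excluded_frac`
#' exclusions abort with an error. Single-feature QDA reports for the
#' derivative feature alone and RMSSD alone are included for comparison.
#'
#' @param cohort A `ppg_cohort`.
#' @param spec [filter_spec()] for filtering and peak detection.
#' @param feature,status,order The derivative feature cell to combine
#'   (defaults: entropy, filtered, order 7).
#' @param classifier Classifier for the combined rule (default `"qda"`).
#' @param features Optional precomputed `ppg_features` table (reused from a
#'   scan to avoid recomputation).
#' @param hrv Optional precomputed [hrv_analysis()] table.
#' @param max_excluded_frac Hard limit on the fraction of recordings without
#'   valid RMSSD.
#'
#' @return Object of class `ppg_combined`: list with per-comparison
#'   `reports` (combined 2-D), `single_feature` and `single_rmssd` reports,
#'   `mean_F1` for each rule, and the exclusion count.
#' @export
run_combined <- function(cohort, spec = filter_spec(), feature = "entropy",
                         status = "filtered", order = 7, classifier = "qda",
                         features = NULL, hrv = NULL,
                         max_excluded_frac = 0.2) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  if (is.null(features)) {
    features <- cohort_features(cohort, spec, max_order = order)
  }
  if (is.null(hrv)) hrv <- hrv_analysis(cohort, spec)
  fsub <- features[features$feature == feature & features$status == status &
                     features$order == order, ]
  if (nrow(fsub) == 0) stop("requested feature cell not in table", call. = FALSE)
  df <- merge(fsub[, c("subject_id", "condition", "value")],
              hrv[, c("subject_id", "condition", "rmssd_ms")],
              by = c("subject_id", "condition"))
  n_excl <- sum(!is.finite(df$rmssd_ms))
  if (n_excl / nrow(df) > max_excluded_frac) {
    stop(sprintf("%d/%d recordings lack a valid RMSSD: cohort too noisy",
                 n_excl, nrow(df)), call. = FALSE)
  }
  df <- df[is.finite(df$rmssd_ms), ]
  stages <- sort(setdiff(unique(df$condition), "BE"))
  eval_rule <- function(cols) {
    reports <- lapply(stages, function(st) {
      sub <- df[df$condition %in% c("BE", st), ]
      x <- as.matrix(sub[, cols, drop = FALSE])
      y <- ifelse(sub$condition == "BE", "before", "after")
      pred <- loocv_predict(x, y, classifier)
      confusion_metrics(pred, y)
    })
    names(reports) <- paste0("BE_vs_", stages)
    reports
  }
  combined <- eval_rule(c("value", "rmssd_ms"))
  single_f <- eval_rule("value")
  single_r <- eval_rule("rmssd_ms")
  mean_f1 <- function(reps) mean(vapply(reps, function(r) r$F1, 0))
  structure(list(
    reports = combined, single_feature = single_f, single_rmssd = single_r,
    mean_F1 = c(combined = mean_f1(combined),
                single_feature = mean_f1(single_f),
                single_rmssd = mean_f1(single_r)),
    cell = list(feature = feature, status = status, order = order),
    classifier = classifier, n_excluded = n_excl
  ), class = "ppg_combined")
}

#' @export
print.ppg_combined <- function(x, ...) {
  cat(sprintf("<ppg_combined> %s(%s, order %d) + RMSSD under %s LOOCV\n",
              x$cell$feature, x$cell$status, x$cell$order, x$classifier))
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    cat(sprintf("  %s: SE %.1f%%  PP %.2f%%  F1 %.1f%%\n",
                nm, r$SE, r$PP, r$F1))
  }
  cat(sprintf("Mean F1: combined %.1f%% | feature alone %.1f%% | RMSSD alone %.1f%%\n",
              x$mean_F1["combined"], x$mean_F1["single_feature"],
              x$mean_F1["single_rmssd"]))
  if (x$n_excluded > 0) {
    cat(sprintf("(%d recording(s) excluded: no valid RMSSD)\n", x$n_excluded))
  }
  invisible(x)
}

#' Write the classifier OA grid as a wide CSV
#'
#' Rows are derivative orders; column blocks are feature-by-status cells
#' with per-comparison OA values and their mean.
#'
#' @param scan A `ppg_scan`.
#' @param file Path to a CSV file.
#' @export
write_oa_grid <- function(scan, file) {
  g <- scan$oa_grid
  orders <- sort(unique(g$order))
  out <- data.frame(order = orders)
  for (f in unique(g$feature)) for (s in unique(g$status)) {
    base <- paste(f, s, sep = "_")
    for (cmp in unique(g$comparison)) {
      sub <- g[g$feature == f & g$status == s & g$comparison == cmp, ]
      out[[paste(base, cmp, sep = "_")]] <- sub$OA[match(orders, sub$order)]
    }
    subm <- scan$oa_cells[scan$oa_cells$feature == f & scan$oa_cells$status == s, ]
    out[[paste0(base, "_OA")]] <- subm$OA[match(orders, subm$order)]
  }
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
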