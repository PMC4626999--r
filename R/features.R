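# Whole-recording features: normalized energy and normalized Shannon
# entropy of every derivative order, filtered and unfiltered.
#
# "Normalized" refers to the 1/N factor: E_j is the mean squared amplitude
# of S_j and P_j is -mean(S_j^2 * ln(S_j^2)). P_j is a signal-randomness
# functional, not a probability entropy: its sign is unrestricted (large
# squared amplitudes drive it negative) and 0 * ln(0) is taken as 0.

#' Normalized energy of a signal
#'
#' Mean of the squared samples, with N the length of the supplied (possibly
#' derivative-shrunk) signal.
#'
#' @param x Numeric vector, length >= 1, finite.
#' @return Non-negative scalar.
#' @examples
#' signal_energy(c(1, 2, 3)) # 14/3
#' @export
signal_energy <- function(x) {
  if (length(x) < 1L) stop("empty signal", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite samples", call. = FALSE)
  mean(x^2)
}

#' Normalized Shannon entropy of a signal
#'
#' `-mean(x^2 * log(x^2))` with natural logarithm and the convention
#' `0 * log(0) = 0`. Unlike a probability entropy this can be negative:
#' squared amplitudes above 1 contribute negative terms.
#'
#' @param x Numeric vector, length >= 1, finite.
#' @return Scalar (unrestricted sign).
#' @examples
#' signal_entropy(c(1, 1, 1)) # 0
#' signal_entropy(sqrt(exp(1))) # -e
#' @export
signal_entropy <- function(x) {
  if (length(x) < 1L) stop("empty signal", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite samples", call. = FALSE)
  s2 <- x^2
  term <- ifelse(s2 > 0, s2 * log(s2), 0)
  out <- -mean(term)
  if (!is.finite(out)) stop("non-finite entropy", call. = FALSE)
  out
}

#' Energy and entropy features across a pair of derivative stacks
#'
#' Fills one recording's feature cells: energy and entropy for every order
#' 0..`max_order` of the unfiltered and filtered derivative stacks
#' (2 features x 2 statuses x 21 orders = 84 cells at the default depth).
#'
#' @param stack_unfiltered,stack_filtered `derivative_stack` objects built
#'   from the same recording before and after bandpass filtering.
#' @param subject_id,condition Labels copied into the output.
#'
#' @return A long-format data frame with columns `subject_id`, `condition`,
#'   `feature` (`"energy"`/`"entropy"`), `status`
#'   (`"unfiltered"`/`"filtered"`), `order`, `value`.
#' @export
extract_features <- function(stack_unfiltered, stack_filtered,
                             subject_id = "S01", condition = "BE") {
  stopifnot(inherits(stack_unfiltered, "derivative_stack"),
            inherits(stack_filtered, "derivative_stack"))
  if (stack_unfiltered$max_order != stack_filtered$max_order) {
    stop("stacks must share max_order", call. = FALSE)
  }
  rows <- list()
  for (status in c("unfiltered", "filtered")) {
    st <- if (status == "unfiltered") stack_unfiltered else stack_filtered
    for (j in 0:st$max_order) {
      s <- st$signals[[j + 1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject_id, condition = condition,
        feature = c("energy", "entropy"), status = status, order = j,
        value = c(signal_energy(s), signal_entropy(s))
      )
    }
  }
  do.call(rbind, rows)
}

#' Feature table for a whole cohort
#'
#' Runs the bandpass filter and both derivative cascades on every recording
#' and extracts all energy/entropy cells.
#'
#' @param cohort A `ppg_cohort`.
#' @param spec A [filter_spec()] for the filtered branch.
#' @param max_order Cascade depth (default 20).
#' @param normalize Scale each recording to unit variance before the
#'   cascades. Off by default — the features are defined on raw amplitudes —
#'   but useful when recordings mix devices with different gain, which would
#'   otherwise leak amplitude scale into the classifiers.
#'
#' @return Long-format data frame of class `ppg_features` (columns as in
#'   [extract_features()]).
#' @export
cohort_features <- function(cohort, spec = filter_spec(), max_order = 20,
                            normalize = FALSE) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  out <- lapply(cohort$recordings, function(r) {
    if (normalize) {
      s <- stats::sd(r$samples)
      if (s > 0) r$samples <- r$samples / s
    }
    raw <- derivative_cascade(r, max_order = max_order, filtered = FALSE)
    filt <- derivative_cascade(bandpass(r, spec), max_order = max_order)
    extract_features(raw, filt, subject_id = r$subject_id,
                     condition = r$condition)
  })
  res <- do.call(rbind, out)
  class(res) <- c("ppg_features", class(res))
  res
}

#' Write / read a feature table as tidy CSV
#'
#' @param features A `ppg_features` data frame.
#' @param file Path to a CSV file.
#' @return `read_features` returns the `ppg_features` data frame.
#' @export
write_features <- function(features, file) {
  utils::write.csv(as.data.frame(features), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_features
#' @export
read_features <- function(file) {
  res <- utils::read.csv(file)
  needed <- c("subject_id", "condition", "feature", "status", "order", "value")
  if (!all(needed %in% names(res))) {
    stop("not a feature table: missing columns", call. = FALSE)
  }
  class(res) <- c("ppg_features", class(res))
  res
}
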