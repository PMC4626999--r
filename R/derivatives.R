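# Recursive first-difference derivative cascade, orders 0..20.
#
# Each step maps S_{i-1} to S_i[n] = (S_{i-1}[n] - S_{i-1}[n-1]) / T with
# T = 1/fs, so the signal shrinks by one sample per order and the gain of a
# pure sinusoid at frequency f grows by |2 sin(pi f / fs)| * fs per order.
# No padding is used: the difference is undefined at the first sample, and
# padded endpoints would inject discontinuities that explode over 20
# differentiations.

#' Single first-difference derivative
#'
#' @param x Numeric vector, length >= 2.
#' @param T Sampling interval in seconds (reciprocal of the sampling rate).
#' @return `diff(x) / T`, one sample shorter than the input.
#' @examples
#' differentiate_once(c(0, 1, 2, 3), T = 1 / 367)
#' @export
differentiate_once <- function(x, T) {
  if (length(x) < 2L) stop("signal must have at least 2 samples", call. = FALSE)
  if (T <= 0) stop("'T' must be positive", call. = FALSE)
  diff(x) / T
}

#' Derivative cascade of a PPG recording
#'
#' Applies [differentiate_once()] recursively, yielding the ordered family
#' S_0 (the input) through S_`max_order`. Units of S_i are input units times
#' s^-i; lengths shrink by one per order.
#'
#' @param recording A `ppg_recording` or numeric vector.
#' @param fs Sampling rate in Hz (taken from the recording if supplied).
#' @param max_order Highest derivative order (default 20).
#' @param filtered Filtering status flag stored in the stack; defaults to the
#'   recording's own flag.
#'
#' @return An object of class `derivative_stack`: list with `signals`
#'   (list of `max_order + 1` vectors), `fs`, `T`, `filtered`, `max_order`.
#' @examples
#' st <- derivative_cascade(c(0, 1, 4, 9, 16), fs = 1, max_order = 2)
#' st$signals[[3]] # second differences
#' @export
derivative_cascade <- function(recording, fs = NULL, max_order = 20,
                               filtered = NULL) {
  if (inherits(recording, "ppg_recording")) {
    x <- recording$samples
    fs <- recording$fs
    if (is.null(filtered)) filtered <- isTRUE(recording$filtered)
  } else {
    x <- as.numeric(recording)
    if (is.null(fs)) stop("'fs' required for a bare numeric vector", call. = FALSE)
    if (is.null(filtered)) filtered <- FALSE
  }
  max_order <- as.integer(max_order)
  if (max_order < 0L) stop("'max_order' must be >= 0", call. = FALSE)
  if (length(x) <= max_order + 1L) {
    stop("recording too short for the requested cascade depth", call. = FALSE)
  }
  T <- 1 / fs
  signals <- vector("list", max_order + 1L)
  signals[[1L]] <- x
  for (i in seq_len(max_order)) {
    s <- differentiate_once(signals[[i]], T)
    if (!all(is.finite(s))) {
      stop(sprintf("non-finite values reached at derivative order %d", i),
           call. = FALSE)
    }
    signals[[i + 1L]] <- s
  }
  structure(list(signals = signals, fs = fs, T = T, filtered = filtered,
                 max_order = max_order),
            class = "derivative_stack")
}

#' @export
print.derivative_stack <- function(x, ...) {
  cat(sprintf("<derivative_stack> orders 0..%d, %s input, %d -> %d samples @ %g Hz\n",
              x$max_order, if (x$filtered) "filtered" else "unfiltered",
              length(x$signals[[1]]), length(x$signals[[x$max_order + 1]]),
              x$fs))
  invisible(x)
}
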