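# Bandpass preprocessing: second-order Butterworth, 0.5-7 Hz by default.
#
# The filter is designed with signal::butter and then refactored into
# cascaded second-order sections (biquads). At fs = 367 Hz the 0.5 Hz edge
# puts poles very close to z = 1, where the expanded direct-form transfer
# function loses precision; filtering biquad-by-biquad keeps each section
# well conditioned.

#' Bandpass filter specification
#'
#' @param low,high Passband edges in Hz (defaults 0.5 and 7).
#' @param order Butterworth order of the underlying lowpass prototype
#'   (default 2; the bandpass has twice as many poles).
#' @param mode `"causal"` for a single forward pass (default) or
#'   `"zero_phase"` for forward-backward filtering (doubles the effective
#'   order and removes group delay).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low = 0.5, high = 7, order = 2,
                        mode = c("causal", "zero_phase")) {
  mode <- match.arg(mode)
  if (!(low > 0 && high > low)) {
    stop("need 0 < low < high", call. = FALSE)
  }
  if (order < 1) stop("'order' must be >= 1", call. = FALSE)
  structure(list(low = low, high = high, order = as.integer(order),
                 mode = mode), class = "filter_spec")
}

# Design the digital Butterworth bandpass and pair its poles/zeros into
# real-coefficient biquads. Returns a list of sections, each with b and a.
butter_sos <- function(low, high, order, fs) {
  if (high >= fs / 2) {
    stop("'high' cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  b <- flt$b
  a <- flt$a
  gain <- b[which(b != 0)[1]] / a[1]
  # roots in z of the numerator/denominator polynomials
  zeros <- polyroot(rev(b / b[which(b != 0)[1]]))
  poles <- polyroot(rev(a / a[1]))
  pair_conj <- function(r) {
    # group roots into conjugate pairs (or pairs of reals)
    r <- r[order(Re(r), Im(r))]
    used <- rep(FALSE, length(r))
    pairs <- list()
    for (i in seq_along(r)) {
      if (used[i]) next
      used[i] <- TRUE
      j <- which(!used & abs(r - Conj(r[i])) < 1e-6)[1]
      if (is.na(j)) j <- which(!used)[1]
      if (is.na(j)) {
        pairs[[length(pairs) + 1L]] <- r[i]
      } else {
        used[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(r[i], r[j])
      }
    }
    pairs
  }
  ppairs <- pair_conj(poles)
  zpairs <- pair_conj(zeros)
  # match each pole pair with the nearest remaining zero pair
  sections <- vector("list", length(ppairs))
  taken <- rep(FALSE, length(zpairs))
  # process pole pairs closest to the unit circle first
  ord <- order(-vapply(ppairs, function(p) max(Mod(p)), 0))
  for (k in ord) {
    p <- ppairs[[k]]
    d <- vapply(seq_along(zpairs), function(j) {
      if (taken[j]) return(Inf)
      min(Mod(outer(p, zpairs[[j]], "-")))
    }, 0)
    j <- which.min(d)
    taken[j] <- TRUE
    z <- zpairs[[j]]
    poly_from <- function(r) {
      if (length(r) == 1L) c(1, -Re(r)) else c(1, -Re(r[1] + r[2]), Re(r[1] * r[2]))
    }
    sections[[k]] <- list(b = poly_from(z), a = poly_from(p))
  }
  sections[[1L]]$b <- sections[[1L]]$b * gain
  sections
}

sos_filter <- function(sections, x) {
  for (s in sections) {
    x <- as.numeric(signal::filter(s$b, s$a, x))
  }
  x
}

#' Bandpass-filter a PPG recording
#'
#' Applies the configured Butterworth bandpass (0.5-7 Hz, order 2 by
#' default), realized as cascaded second-order sections. Causal single-pass
#' filtering is the default; `mode = "zero_phase"` runs the cascade forward
#' and backward, cancelling phase distortion at the cost of doubling the
#' magnitude response's order. Output length equals input length; no
#' transient samples are trimmed.
#'
#' @param recording A `ppg_recording` (or numeric vector if `fs` is given).
#' @param spec A [filter_spec()].
#' @param fs Sampling rate, only needed when `recording` is a bare vector.
#'
#' @return Same type as the input: a `ppg_recording` with `filtered = TRUE`,
#'   or a numeric vector.
#' @examples
#' rec <- ppg_recording(sin(2 * pi * 3 * (0:999) / 367), fs = 367)
#' filt <- bandpass(rec)
#' @export
bandpass <- function(recording, spec = filter_spec(), fs = NULL) {
  if (inherits(recording, "ppg_recording")) {
    x <- recording$samples
    fs <- recording$fs
  } else {
    x <- as.numeric(recording)
    if (is.null(fs)) stop("'fs' required for a bare numeric vector", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("non-finite samples in input", call. = FALSE)
  if (spec$high >= fs / 2) {
    stop("filter cutoffs must be below the Nyquist frequency", call. = FALSE)
  }
  sections <- butter_sos(spec$low, spec$high, spec$order, fs)
  # remove the onset step before filtering: the DC gain is zero, so
  # subtracting the first sample changes nothing in steady state but
  # avoids exciting the slow 0.5 Hz transient with a discontinuity
  y <- sos_filter(sections, x - x[1])
  if (spec$mode == "zero_phase") {
    yr <- rev(y)
    y <- rev(sos_filter(sections, yr - yr[1]))
  }
  if (inherits(recording, "ppg_recording")) {
    out <- recording
    out$samples <- y
    out$filtered <- TRUE
    out
  } else {
    y
  }
}

#' Magnitude response of the configured bandpass
#'
#' Evaluates the realized cascade's complex frequency response at the given
#' frequencies; useful for verifying the design against the analytic
#' Butterworth magnitude curve.
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz.
#' @param freqs Frequencies in Hz.
#' @return Numeric vector of magnitude gains (zero-phase mode squares them).
#' @export
bandpass_gain <- function(spec, fs, freqs) {
  sections <- butter_sos(spec$low, spec$high, spec$order, fs)
  z <- exp(1i * 2 * pi * freqs / fs)
  h <- rep(1 + 0i, length(z))
  for (s in sections) {
    num <- outer(z, 0:(length(s$b) - 1), function(zz, k) zz^(-k)) %*% s$b
    den <- outer(z, 0:(length(s$a) - 1), function(zz, k) zz^(-k)) %*% s$a
    h <- h * as.vector(num) / as.vector(den)
  }
  g <- Mod(h)
  if (spec$mode == "zero_phase") g <- g^2
  g
}
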