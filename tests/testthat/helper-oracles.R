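# Independent oracles and fixture builders used across the suite.

# From-definition Holm step-down: sort ascending, compare p_(k) against
# alpha / (m - k + 1); rejections are the maximal prefix of the sorted
# order; adjusted p_(k) is the running max of min(1, (m - k + 1) p_(k)).
oracle_holm <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  run <- 0
  for (k in seq_len(m)) {
    run <- max(run, min(1, (m - k + 1) * p[ord[k]]))
    adj_sorted[k] <- run
  }
  rej_sorted <- logical(m)
  for (k in seq_len(m)) {
    if (p[ord[k]] <= alpha / (m - k + 1)) rej_sorted[k] <- TRUE else break
  }
  adj <- numeric(m); rej <- logical(m)
  adj[ord] <- adj_sorted
  rej[ord] <- rej_sorted
  list(adjusted = adj, reject = rej)
}

# Brute-force two-sided Mann-Whitney by enumeration of group assignments,
# built on the U statistic (count of x > y pairs, ties as 1/2) rather than
# rank sums, so it is an independent construction from the implementation.
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled)
  n <- length(x)
  u_stat <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(seq_len(n))
  U <- apply(utils::combn(N, n), 2, u_stat)
  eps <- 1e-9
  min(1, 2 * min(mean(U <= u_obs + eps), mean(U >= u_obs - eps)))
}

# Clean synthetic recording with known beat structure.
make_clean_recording <- function(hr = 75, duration = 20, fs = 367,
                                 rmssd = 30, seed = 1, noise = 0, ...) {
  ibis <- generate_ibi_sequence(hr, rmssd, duration + 1, seed = seed)
  pt <- render_pulse_train(ibis, fs, duration = duration, ...)
  samples <- if (noise > 0) {
    add_ppg_noise(pt$samples, fs, white_sigma = noise, seed = seed + 1000)
  } else pt$samples
  list(rec = ppg_recording(samples, fs, true_peak_times = pt$peak_times),
       peaks = pt$peak_times)
}

# Match detections to annotations within a tolerance; returns counts.
match_peaks <- function(detected, truth, tol = 0.025) {
  tp <- 0
  used <- rep(FALSE, length(detected))
  for (t in truth) {
    d <- abs(detected - t)
    j <- which(!used & d <= tol)
    if (length(j)) {
      used[j[which.min(d[j])]] <- TRUE
      tp <- tp + 1
    }
  }
  list(tp = tp, fn = length(truth) - tp, fp = sum(!used))
}

small_config <- function(n_subjects = 6, n_stages = 1, seed = 11, ...) {
  synth_config(n_subjects = n_subjects, n_stages = n_stages, seed = seed, ...)
}

# Null cohort: stress stages generated with the rest parameters.
null_config <- function(n_subjects = 10, seed = 1, n_stages = 1) {
  synth_config(
    n_subjects = n_subjects, n_stages = n_stages, seed = seed,
    hr_stress = rep(76, n_stages), hr_stress_disp = rep(13, n_stages),
    rmssd_stress = 40, dicrotic_amplitude_stress = 0.35,
    pulse_width_stress = 0.09
  )
}
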