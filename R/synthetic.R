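# Synthetic rest vs heat-stress PPG cohort generator.
#
# The generator emulates a cohort of subjects each recorded once at rest (BE)
# and once after each of up to three exertional heat-stress stages (E1-E3):
# elevated heart rate, suppressed RMSSD, subtly altered pulse morphology
# (smaller dicrotic wave, narrower systolic upstroke), plus baseline wander,
# powerline interference and broadband noise.

#' Configuration for the synthetic PPG cohort generator
#'
#' Collects every knob of the simulated study: cohort size, recording
#' parameters, per-condition heart-rate and RMSSD targets, pulse morphology,
#' and additive noise amplitudes. Defaults reproduce a resting median heart
#' rate of 76 bpm against post-exercise medians of 132, 145.5 and 143 bpm
#' (dispersions derived from interquartile ranges), with rest RMSSD around
#' 40 ms suppressed to about 15 ms under heat stress.
#'
#' @param n_subjects Number of subjects (>= 2); each yields one `BE` plus one
#'   recording per stress stage.
#' @param fs Sampling rate in Hz.
#' @param duration Recording length in seconds.
#' @param hr_rest,hr_rest_disp Resting heart-rate centre and dispersion
#'   (standard deviation), bpm.
#' @param hr_stress,hr_stress_disp Heart-rate centres and dispersions for the
#'   stress stages, bpm; recycled to `n_stages`.
#' @param rmssd_rest,rmssd_stress RMSSD targets in ms at rest and under
#'   stress.
#' @param rmssd_cv Lognormal coefficient of variation of per-subject RMSSD
#'   around its target.
#' @param dicrotic_amplitude_rest,dicrotic_amplitude_stress Relative dicrotic
#'   wave amplitude in `[0, 1]`.
#' @param pulse_width_rest,pulse_width_stress Systolic Gaussian width
#'   (standard deviation) in seconds.
#' @param noise_baseline_amp Amplitude of the 0.2-0.4 Hz baseline-wander
#'   sinusoid, relative to unit pulse amplitude.
#' @param noise_powerline_amp Amplitude of the powerline sinusoid.
#' @param noise_white_sigma Standard deviation of additive white noise.
#' @param powerline_hz Powerline frequency in Hz (50 by default).
#' @param n_stages Number of stress stages to generate (1-3).
#' @param seed Integer seed governing the whole cohort.
#'
#' @return An object of class `synth_config` (a named list).
#' @examples
#' cfg <- synth_config(n_subjects = 4, seed = 7)
#' cfg$hr_stress
#' @export
synth_config <- function(n_subjects = 40,
                         fs = 367,
                         duration = 20,
                         hr_rest = 76,
                         hr_rest_disp = 13,
                         hr_stress = c(132, 145.5, 143),
                         hr_stress_disp = c(33, 30, 30),
                         rmssd_rest = 40,
                         rmssd_stress = 15,
                         rmssd_cv = 0.25,
                         dicrotic_amplitude_rest = 0.35,
                         dicrotic_amplitude_stress = 0.15,
                         pulse_width_rest = 0.09,
                         pulse_width_stress = 0.065,
                         noise_baseline_amp = 0.2,
                         noise_powerline_amp = 0.02,
                         noise_white_sigma = 0.05,
                         powerline_hz = 50,
                         n_stages = 3,
                         seed = 1L) {
  n_stages <- as.integer(n_stages)
  if (n_stages < 1L || n_stages > 3L) {
    stop("'n_stages' must be 1, 2 or 3", call. = FALSE)
  }
  hr_stress <- rep_len(hr_stress, n_stages)
  hr_stress_disp <- rep_len(hr_stress_disp, n_stages)
  if (n_subjects < 2) stop("'n_subjects' must be at least 2", call. = FALSE)
  if (fs <= 0) stop("'fs' must be positive", call. = FALSE)
  if (duration <= 0) stop("'duration' must be positive", call. = FALSE)
  for (hr in c(hr_rest, hr_stress)) {
    if (hr <= 30 || hr >= 220) {
      stop("heart-rate centres must lie in (30, 220) bpm", call. = FALSE)
    }
  }
  if (rmssd_rest <= 0 || rmssd_stress <= 0) {
    stop("RMSSD targets must be positive", call. = FALSE)
  }
  amps <- c(dicrotic_amplitude_rest, dicrotic_amplitude_stress,
            noise_baseline_amp, noise_powerline_amp, noise_white_sigma)
  if (any(amps < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  if (dicrotic_amplitude_rest > 1 || dicrotic_amplitude_stress > 1) {
    stop("dicrotic amplitudes are relative units in [0, 1]", call. = FALSE)
  }
  if (pulse_width_rest <= 0 || pulse_width_stress <= 0) {
    stop("pulse widths must be positive", call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects), fs = fs, duration = duration,
    hr_rest = hr_rest, hr_rest_disp = hr_rest_disp,
    hr_stress = hr_stress, hr_stress_disp = hr_stress_disp,
    rmssd_rest = rmssd_rest, rmssd_stress = rmssd_stress,
    rmssd_cv = rmssd_cv,
    dicrotic_amplitude_rest = dicrotic_amplitude_rest,
    dicrotic_amplitude_stress = dicrotic_amplitude_stress,
    pulse_width_rest = pulse_width_rest,
    pulse_width_stress = pulse_width_stress,
    noise_baseline_amp = noise_baseline_amp,
    noise_powerline_amp = noise_powerline_amp,
    noise_white_sigma = noise_white_sigma,
    powerline_hz = powerline_hz,
    n_stages = n_stages,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Construct a PPG recording object
#'
#' The unit of analysis: one single-channel PPG sample vector with its
#' sampling rate and study labels. Synthetic recordings additionally carry
#' ground-truth systolic peak times for detector benchmarking.
#'
#' @param samples Numeric amplitude vector (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param condition One of `"BE"`, `"E1"`, `"E2"`, `"E3"`.
#' @param true_peak_times Optional annotated systolic peak times in seconds.
#' @param filtered Logical; has the signal been bandpass filtered?
#'
#' @return An object of class `ppg_recording`.
#' @export
ppg_recording <- function(samples, fs, subject_id = "S01", condition = "BE",
                          true_peak_times = NULL, filtered = FALSE) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("'samples' must be a non-empty numeric vector", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("'samples' must be finite", call. = FALSE)
  }
  if (fs <= 0) stop("'fs' must be positive", call. = FALSE)
  condition <- match.arg(condition, c("BE", "E1", "E2", "E3"))
  structure(list(samples = as.numeric(samples), fs = fs,
                 subject_id = subject_id, condition = condition,
                 true_peak_times = true_peak_times, filtered = filtered),
            class = "ppg_recording")
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat(sprintf("<ppg_recording> subject %s, condition %s: %d samples @ %g Hz (%.1f s)%s\n",
              x$subject_id, x$condition, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (isTRUE(x$filtered)) ", bandpass filtered" else ""))
  invisible(x)
}

#' @export
plot.ppg_recording <- function(x, ...) {
  t <- seq_along(x$samples) / x$fs
  graphics::plot(t, x$samples, type = "l", xlab = "time (s)",
                 ylab = "PPG amplitude (a.u.)",
                 main = sprintf("%s / %s", x$subject_id, x$condition), ...)
  if (!is.null(x$true_peak_times)) {
    graphics::abline(v = x$true_peak_times, col = "grey70", lty = 3)
  }
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. With seed = NULL the global stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate an inter-beat-interval sequence with a target RMSSD
#'
#' Beat-to-beat intervals are the base interval `60 / hr_bpm` plus
#' independent Gaussian jitter with standard deviation
#' `rmssd_target / sqrt(2)`, the scaling for which i.i.d. jitter attains the
#' requested RMSSD in expectation (RMSSD of i.i.d. perturbations equals
#' `sqrt(2)` times their standard deviation). Intervals are emitted until
#' their sum covers `duration`.
#'
#' @param hr_bpm Mean heart rate in bpm, in (30, 220).
#' @param rmssd_target Target RMSSD in ms (>= 0; 0 disables jitter).
#' @param duration Minimum total duration to cover, in seconds.
#' @param seed Optional integer seed for a local RNG stream.
#'
#' @return Numeric vector of intervals in seconds; `sum(...) >= duration`.
#' @examples
#' ibis <- generate_ibi_sequence(76, 40, 20, seed = 1)
#' 60 / mean(ibis) # realized heart rate, bpm
#' @export
generate_ibi_sequence <- function(hr_bpm, rmssd_target, duration, seed = NULL) {
  if (hr_bpm <= 30 || hr_bpm >= 220) {
    stop("'hr_bpm' must lie in (30, 220)", call. = FALSE)
  }
  if (rmssd_target < 0) stop("'rmssd_target' must be >= 0", call. = FALSE)
  if (duration <= 0) stop("'duration' must be positive", call. = FALSE)
  with_seed(seed, {
    base <- 60 / hr_bpm
    sigma <- (rmssd_target / 1000) / sqrt(2)
    n <- ceiling(duration / base) + 8L
    ibis <- numeric(0)
    repeat {
      draw <- base + stats::rnorm(n, 0, sigma)
      # guard against non-physiologic draws when sigma is large vs base
      draw <- pmax(draw, 0.25 * base)
      ibis <- c(ibis, draw)
      if (sum(ibis) >= duration) break
    }
    k <- which(cumsum(ibis) >= duration)[1L]
    ibis[seq_len(k)]
  })
}

#' Render a pulse train from inter-beat intervals
#'
#' Each beat is a two-Gaussian template: a systolic peak of unit relative
#' amplitude and a delayed, lower dicrotic wave at a configurable fraction of
#' the local beat interval. Summing templates over the beat sequence gives a
#' clean PPG-like waveform; annotated systolic peak times are returned for
#' detector validation.
#'
#' @param ibis Inter-beat intervals in seconds (non-empty, positive).
#' @param fs Sampling rate in Hz.
#' @param duration Output duration in seconds; defaults to `t0 + sum(ibis)`.
#' @param amplitude Systolic peak amplitude (arbitrary units).
#' @param pulse_width Systolic Gaussian standard deviation, seconds.
#' @param dicrotic_amplitude Dicrotic amplitude relative to systolic, `[0, 1]`.
#' @param dicrotic_delay_frac Dicrotic delay as a fraction of the local beat
#'   interval.
#' @param dicrotic_width Dicrotic Gaussian standard deviation, seconds.
#' @param t0 Time of the first systolic peak, seconds.
#'
#' @return List with `samples` (length `round(fs * duration)`) and
#'   `peak_times` (systolic peak times within the recording).
#' @export
render_pulse_train <- function(ibis, fs, duration = NULL, amplitude = 1,
                               pulse_width = 0.09,
                               dicrotic_amplitude = 0.35,
                               dicrotic_delay_frac = 0.35,
                               dicrotic_width = 0.13,
                               t0 = 0.3) {
  if (length(ibis) < 1L) stop("'ibis' must be non-empty", call. = FALSE)
  if (any(ibis <= 0)) stop("'ibis' must be positive", call. = FALSE)
  if (fs <= 0) stop("'fs' must be positive", call. = FALSE)
  if (pulse_width <= 0 || dicrotic_width <= 0) {
    stop("morphology widths must be positive", call. = FALSE)
  }
  if (is.null(duration)) duration <- t0 + sum(ibis)
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  peaks <- t0 + c(0, cumsum(ibis))
  local_ibi <- c(ibis, ibis[length(ibis)])
  keep <- peaks <= duration
  peaks <- peaks[keep]
  local_ibi <- local_ibi[keep]
  x <- numeric(n)
  for (k in seq_along(peaks)) {
    x <- x + amplitude * exp(-(t - peaks[k])^2 / (2 * pulse_width^2))
    if (dicrotic_amplitude > 0) {
      dc <- peaks[k] + dicrotic_delay_frac * local_ibi[k]
      x <- x + amplitude * dicrotic_amplitude *
        exp(-(t - dc)^2 / (2 * dicrotic_width^2))
    }
  }
  # the dicrotic shoulder skews each beat slightly; annotate the true local
  # maximum of the composite waveform rather than the systolic centre
  peaks <- peaks[peaks < duration]
  refined <- vapply(peaks, function(p) {
    i <- round(p * fs) + 1
    w <- round(0.04 * fs)
    lo <- max(1L, i - w); hi <- min(n, i + w)
    (lo + which.max(x[lo:hi]) - 2) / fs
  }, 0)
  list(samples = x, peak_times = refined)
}

#' Add baseline wander, powerline interference and white noise
#'
#' The three noise classes that contaminate fingertip PPG in practice:
#' a slow 0.2-0.4 Hz baseline-wander sinusoid (respiration/motion), a
#' powerline sinusoid (50 Hz by default) and broadband Gaussian noise.
#' With all amplitudes zero the input is returned exactly.
#'
#' @param x Clean amplitude vector.
#' @param fs Sampling rate in Hz.
#' @param baseline_amp,powerline_amp Sinusoid amplitudes (signal units).
#' @param baseline_freq Baseline-wander frequency in Hz; drawn uniformly in
#'   `[0.2, 0.4]` when `NULL`.
#' @param powerline_hz Powerline frequency in Hz.
#' @param white_sigma White-noise standard deviation.
#' @param seed Optional integer seed for a local RNG stream.
#'
#' @return Noisy amplitude vector, same length as `x`.
#' @export
add_ppg_noise <- function(x, fs, baseline_amp = 0, powerline_amp = 0,
                          white_sigma = 0, baseline_freq = NULL,
                          powerline_hz = 50, seed = NULL) {
  if (any(c(baseline_amp, powerline_amp, white_sigma) < 0)) {
    stop("noise amplitudes must be non-negative", call. = FALSE)
  }
  with_seed(seed, {
    n <- length(x)
    t <- (seq_len(n) - 1) / fs
    out <- x
    if (baseline_amp > 0) {
      f <- if (is.null(baseline_freq)) stats::runif(1, 0.2, 0.4) else baseline_freq
      out <- out + baseline_amp * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    }
    if (powerline_amp > 0) {
      out <- out + powerline_amp *
        sin(2 * pi * powerline_hz * t + stats::runif(1, 0, 2 * pi))
    }
    if (white_sigma > 0) out <- out + stats::rnorm(n, 0, white_sigma)
    out
  })
}

#' Generate a synthetic rest/heat-stress PPG cohort
#'
#' Draws per-subject heart-rate and RMSSD parameters for rest (`BE`) and each
#' stress stage (`E1`..), renders the corresponding pulse trains and adds
#' noise. Heat stress manifests as elevated heart rate, suppressed RMSSD,
#' a smaller dicrotic wave and a narrower systolic upstroke. The whole cohort
#' is a deterministic function of `config` (including `config$seed`).
#'
#' @param config A [synth_config()] object.
#'
#' @return An object of class `ppg_cohort`: list with `recordings` (one
#'   `ppg_recording` per subject x condition) and the `config` snapshot.
#' @examples
#' coh <- generate_cohort(synth_config(n_subjects = 3, n_stages = 1, seed = 2))
#' coh
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop("'config' must be a synth_config object", call. = FALSE)
  }
  with_seed(config$seed, {
    recs <- list()
    conditions <- c("BE", paste0("E", seq_len(config$n_stages)))
    hr_centres <- c(config$hr_rest, config$hr_stress)
    hr_disp <- c(config$hr_rest_disp, config$hr_stress_disp)
    rmssd_tgt <- c(config$rmssd_rest, rep(config$rmssd_stress, config$n_stages))
    dic_amp <- c(config$dicrotic_amplitude_rest,
                 rep(config$dicrotic_amplitude_stress, config$n_stages))
    p_width <- c(config$pulse_width_rest,
                 rep(config$pulse_width_stress, config$n_stages))
    for (s in seq_len(config$n_subjects)) {
      sid <- sprintf("S%02d", s)
      for (ci in seq_along(conditions)) {
        hr <- rnorm_trunc(hr_centres[ci], hr_disp[ci], 45, 200)
        rmssd <- rmssd_tgt[ci] *
          exp(stats::rnorm(1, 0, config$rmssd_cv) - config$rmssd_cv^2 / 2)
        amp <- exp(stats::rnorm(1, 0, 0.1))
        ibis <- generate_ibi_sequence(hr, rmssd, config$duration + 1)
        pt <- render_pulse_train(
          ibis, config$fs, duration = config$duration, amplitude = amp,
          pulse_width = p_width[ci], dicrotic_amplitude = dic_amp[ci]
        )
        noisy <- add_ppg_noise(
          pt$samples, config$fs,
          baseline_amp = config$noise_baseline_amp * amp,
          powerline_amp = config$noise_powerline_amp * amp,
          white_sigma = config$noise_white_sigma * amp,
          powerline_hz = config$powerline_hz
        )
        recs[[length(recs) + 1L]] <- ppg_recording(
          noisy, config$fs, subject_id = sid, condition = conditions[ci],
          true_peak_times = pt$peak_times
        )
      }
    }
    structure(list(recordings = recs, config = config), class = "ppg_cohort")
  })
}

rnorm_trunc <- function(mean, sd, lo, hi) {
  for (i in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (x > lo && x < hi) return(x)
  }
  min(max(mean, lo), hi)
}

#' @export
print.ppg_cohort <- function(x, ...) {
  conds <- vapply(x$recordings, function(r) r$condition, "")
  cat(sprintf("<ppg_cohort> %d subjects, %d recordings @ %g Hz, %g s each\n",
              x$config$n_subjects, length(x$recordings), x$config$fs,
              x$config$duration))
  print(table(condition = conds))
  invisible(x)
}

#' Write / read a cohort as plain CSV files
#'
#' One CSV per recording (single `ppg` column; a `# fs=<Hz>` comment header),
#' an optional `<stem>_peaks.csv` with annotated peak times, and a
#' `manifest.csv` tying subject, condition and file together.
#'
#' @param cohort A `ppg_cohort`.
#' @param dir Output directory (created if missing).
#' @return `write_cohort` returns the manifest data frame invisibly;
#'   `read_cohort` returns a `ppg_cohort` (with a minimal config snapshot).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort$recordings, function(r) {
    stem <- sprintf("%s_%s", r$subject_id, r$condition)
    f <- file.path(dir, paste0(stem, ".csv"))
    con <- file(f, "w")
    writeLines(sprintf("# fs=%g", r$fs), con)
    utils::write.csv(data.frame(ppg = r$samples), con, row.names = FALSE)
    close(con)
    if (!is.null(r$true_peak_times)) {
      utils::write.csv(data.frame(peak_time_s = r$true_peak_times),
                       file.path(dir, paste0(stem, "_peaks.csv")),
                       row.names = FALSE)
    }
    data.frame(subject_id = r$subject_id, condition = r$condition,
               file = basename(f), fs = r$fs)
  })
  manifest <- do.call(rbind, rows)
  manifest$seed <- cohort$config$seed
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    f <- file.path(dir, manifest$file[i])
    samples <- utils::read.csv(f, comment.char = "#")$ppg
    pk_file <- file.path(dir, sub("\\.csv$", "_peaks.csv", manifest$file[i]))
    peaks <- if (file.exists(pk_file)) utils::read.csv(pk_file)$peak_time_s else NULL
    ppg_recording(samples, manifest$fs[i],
                  subject_id = manifest$subject_id[i],
                  condition = manifest$condition[i],
                  true_peak_times = peaks)
  })
  cfg <- list(n_subjects = length(unique(manifest$subject_id)),
              fs = manifest$fs[1],
              duration = length(recs[[1]]$samples) / manifest$fs[1],
              seed = if ("seed" %in% names(manifest)) manifest$seed[1] else NA)
  structure(list(recordings = recs, config = cfg), class = "ppg_cohort")
}
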