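test_that("IBI sequences hit their heart-rate and RMSSD targets", {
  # zero-jitter limit: all intervals equal the base interval
  ibis0 <- generate_ibi_sequence(76, 0, 20, seed = 1)
  expect_true(all(abs(ibis0 - 60 / 76) < 1e-12))
  expect_equal(rmssd(cumsum(c(0, ibis0))), 0)

  # realized mean HR within 5% of target on a long sequence
  ibis <- generate_ibi_sequence(76, 40, 300, seed = 42)
  expect_gte(sum(ibis), 300)
  hr <- 60 / mean(ibis)
  expect_gt(hr, 72.2)
  expect_lt(hr, 79.8)

  # realized RMSSD within 15% of target for a long sequence
  r <- rmssd(cumsum(c(0, ibis)), gate = NULL)
  expect_lt(abs(r - 40) / 40, 0.15)

  # seeded determinism
  expect_identical(generate_ibi_sequence(76, 40, 20, seed = 7),
                   generate_ibi_sequence(76, 40, 20, seed = 7))

  expect_error(generate_ibi_sequence(76, -1, 20), "rmssd")
  expect_error(generate_ibi_sequence(10, 40, 20), "hr_bpm")
})

test_that("pulse trains place one annotated systolic peak per beat", {
  fs <- 367
  pt <- render_pulse_train(rep(0.8, 25), fs, duration = 20)
  expect_length(pt$peak_times, 25)
  expect_true(all(abs(diff(pt$peak_times) - 0.8) <= 1 / fs))
  expect_length(pt$samples, round(20 * fs))

  # annotation fidelity: local maxima of the clean signal within 1 sample
  x <- pt$samples
  for (p in pt$peak_times[-c(1, 25)]) {
    i <- round(p * fs) + 1
    win <- x[(i - 20):(i + 20)]
    expect_lte(abs(which.max(win) - 21), 1)
  }

  # linearity: doubling amplitude scales output exactly
  pt2 <- render_pulse_train(rep(0.8, 25), fs, duration = 20, amplitude = 2)
  expect_equal(pt2$samples, 2 * pt$samples, tolerance = 1e-12)

  # degenerate template: no dicrotic wave -> unimodal beats
  pt0 <- render_pulse_train(rep(0.8, 10), fs, dicrotic_amplitude = 0)
  x0 <- pt0$samples
  mids <- head(pt0$peak_times, -1) + 0.4
  for (m in mids) {
    lo <- round((m - 0.39) * fs); hi <- round((m + 0.38) * fs)
    win <- x0[lo:hi]
    n_max <- sum(diff(sign(diff(win))) < 0)
    expect_lte(n_max, 1)
  }

  expect_error(render_pulse_train(numeric(0), fs), "non-empty")
})

test_that("noise model adds the configured components and nothing else", {
  fs <- 367
  x <- sin(2 * pi * (0:7339) / fs)
  expect_identical(add_ppg_noise(x, fs, seed = 3), x)

  # powerline-only: periodogram peak at 50 Hz with the configured amplitude
  a <- 0.25
  y <- add_ppg_noise(rep(0, fs * 20), fs, powerline_amp = a, seed = 5)
  n <- length(y)
  spec_amp <- 2 * Mod(stats::fft(y)) / n
  fgrid <- (seq_len(n) - 1) * fs / n
  k <- which.max(spec_amp[fgrid < fs / 2])
  expect_lt(abs(fgrid[k] - 50), 0.1)
  expect_lt(abs(spec_amp[k] - a) / a, 0.1)

  expect_identical(add_ppg_noise(x, fs, white_sigma = 0.1, seed = 9),
                   add_ppg_noise(x, fs, white_sigma = 0.1, seed = 9))
  expect_error(add_ppg_noise(x, fs, white_sigma = -1), "non-negative")
})

test_that("cohort generation is complete, labelled and deterministic", {
  cfg <- small_config(n_subjects = 4, n_stages = 3, seed = 21)
  coh <- generate_cohort(cfg)
  expect_length(coh$recordings, 16)
  conds <- vapply(coh$recordings, function(r) r$condition, "")
  sids <- vapply(coh$recordings, function(r) r$subject_id, "")
  expect_equal(unname(table(conds)), rep(4L, 4), ignore_attr = TRUE)
  for (s in unique(sids)) {
    expect_setequal(conds[sids == s], c("BE", "E1", "E2", "E3"))
  }
  expect_true(all(vapply(coh$recordings, function(r)
    length(r$samples) == round(cfg$fs * cfg$duration), TRUE)))

  coh2 <- generate_cohort(cfg)
  expect_identical(coh, coh2)
})

test_that("stress recordings show suppressed RMSSD and the gap is monotone in the target", {
  gaps <- vapply(c(15, 25, 35), function(rs) {
    coh <- generate_cohort(small_config(n_subjects = 8, seed = 5,
                                        rmssd_stress = rs))
    h <- hrv_analysis(coh)
    med <- tapply(h$rmssd_ms, h$condition, stats::median, na.rm = TRUE)
    med[["BE"]] - med[["E1"]]
  }, 0)
  expect_true(all(diff(gaps) < 0)) # gap shrinks toward the rest target
  expect_gt(gaps[1], 0)
})

test_that("cohort CSV round-trips through write_cohort/read_cohort", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(small_config(n_subjects = 2, seed = 8))
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_length(back$recordings, length(coh$recordings))
  expect_equal(back$recordings[[1]]$samples, coh$recordings[[1]]$samples,
               tolerance = 1e-12)
  expect_equal(back$recordings[[1]]$true_peak_times,
               coh$recordings[[1]]$true_peak_times, tolerance = 1e-12)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_subjects = 1), "n_subjects")
  expect_error(synth_config(hr_rest = 250), "heart-rate")
  expect_error(synth_config(rmssd_rest = 0), "RMSSD")
  expect_error(synth_config(noise_white_sigma = -0.1), "non-negative")
})
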