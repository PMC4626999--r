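---
title: "Whole-recording PPG analysis for heat-stress detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-recording PPG analysis for heat-stress detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgheat)
```

## The problem

Exertional heat stress raises heart rate and suppresses vagally mediated
heart rate variability. Both effects leave traces in a fingertip
photoplethysmogram (PPG), but classical PPG analysis requires beat-by-beat
waveform delineation, which is fragile on short, noisy field recordings.
`ppgheat` implements an alternative: treat the *whole* 20-second recording
as the analysis unit, differentiate it repeatedly to accentuate contour
changes, and summarize each derivative order by two scalar functionals —
normalized energy and normalized Shannon entropy. A systematic scan over
derivative orders, for both raw and bandpass-filtered input, identifies the
most informative derivative for separating rest from post-exertion
recordings; the winning feature can then be fused with RMSSD in a quadratic
classifier.

Because the underlying field recordings (40 emergency responders, 367 Hz,
20 s per condition) are not publicly deposited, the package ships a
synthetic cohort generator that reproduces the statistical structure the
method assumes, and the whole pipeline is validated end-to-end against it.

## The pipeline

### Derivative cascade

The cascade applies the scaled first difference

$$ S_i[n] = \frac{S_{i-1}[n] - S_{i-1}[n-1]}{T}, \qquad T = 1/f_s, $$

recursively for $i = 1, \dots, 20$, to both the raw signal $S_0$ and its
bandpass-filtered version. Each step shortens the signal by one sample; we
deliberately do not pad, because the difference is undefined at the first
sample and any padded discontinuity would be amplified roughly
$(2f_s)^{20}$-fold over the cascade. The $1/T$ scaling is retained at every
step even though the downstream rank tests are invariant to it — it keeps
the stack in physical units (input units $\times\, s^{-i}$).

For a pure sinusoid at frequency $f$ the cascade has the closed-form gain
$|2\sin(\pi f/f_s)\, f_s|^{\,i}$, which the test suite uses as an oracle.
One numerical caveat is worth recording: the per-step gain at low in-band
frequencies is far below 1 (about 0.12 before the $1/T$ scaling at 7 Hz and
367 Hz), while double-precision round-off injected at any step is amplified
by up to $2$ per step at Nyquist. Beyond roughly order 10, the round-off
floor overtakes the shrinking in-band component, so the closed form is
verifiable to order 20 only at frequencies whose per-step gain is near or
above 1 (tests use 50–150 Hz). This is a property of finite differences in
finite precision, not of the implementation. Worst-case magnitudes at order
20 for unit-amplitude content stay below $10^{60}$, so squares remain far
from overflow.

### Bandpass filter

The filtered branch uses a second-order Butterworth bandpass, 0.5–7 Hz, the
band commonly found optimal for systolic-peak structure. At
$f_s = 367$ Hz the 0.5 Hz edge places poles within $10^{-2}$ of $z = 1$,
where the expanded 4th-order transfer function is ill-conditioned, so the
design (delegated to `signal::butter`) is refactored into cascaded biquads
by pole/zero pairing before filtering. Filtering is causal and single-pass
by default; a `zero_phase` forward–backward mode is available because it is
common in PPG work, but it doubles the effective magnitude order and is
flagged as a non-default mode. No transient samples are trimmed; instead
the onset step is removed by subtracting the first sample before filtering
(the bandpass has zero DC gain, so steady-state output is unchanged). The
realized response is tested against the analytic Butterworth magnitude
curve at ten probe frequencies.

### Features

For the order-$j$ signal of length $N$ (the shrunk length, since those are
the samples being summed):

$$ E_j = \frac1N \sum_n S_j[n]^2, \qquad
   P_j = -\frac1N \sum_n S_j[n]^2 \log_e S_j[n]^2 . $$

$P_j$ is a signal-randomness functional, not a probability entropy: its
sign is unrestricted, and $0\log 0$ is taken as 0. "Normalized" refers to
the $1/N$ factor only — no amplitude pre-normalization is applied, matching
the definition of the features (an optional per-recording unit-variance
flag exists for cohorts mixing devices with different gain, off by
default). With 2 features, 2 filtering statuses and
orders $0..20$ there are 84 cells per recording. (Order 0 is included: the
feature count is sometimes quoted as 80 by counting only 20 orders, but the
order range is defined as $[0, 20]$ and order 0 carries information, so all
21 orders are computed; the screening family is configurable to exclude
order 0, giving the 240-test family.)

### Screening and correction

Every cell is screened with the unpaired two-sided Wilcoxon–Mann–Whitney
test, rest (BE) against each stress stage, and the three p-values are
averaged per cell. For combined sample sizes up to 12 the p-value is an
exact permutation enumeration (valid under ties); above that, the
tie-corrected normal approximation with continuity correction. Holm's
step-down correction is applied across the family of all computed tests
(252 by default; 240 with the `orders_1_20` family). A paired signed-rank
option exists because parts of the source analyses describe a "paired"
test, but the unpaired test is the default, matching the explicit
description of two independent 40-value sets.

### Classifier benchmark

Each cell is evaluated by leave-one-recording-out cross-validation of four
classifiers: nearest-class Mahalanobis distance (per-class covariance,
trace-scaled ridge on degeneracy), LDA and QDA with equal priors, and a
linear SVM with $C = 1$ and per-fold train-only standardization. Sensitivity
is $100\,TP/(TP+FN)$, positive predictivity $100\,TP/(TP+FP)$, and
$F_1 = 2\,SE\cdot PP/(SE+PP)$, with "after heat stress" the positive class.
The overall accuracy (OA) of a cell is the mean $F_1$ across the four
classifiers; the scan reports the argmax-OA cell per feature-by-status
block and overall. Columns that are constant within a training fold are
dropped before fitting (they carry no discriminant information and break
covariance estimates); an exactly tied Mahalanobis decision predicts
"before", deterministically. Leave-one-*subject*-out would be the stricter
scheme (a subject's rest and stress recordings are not independent) and is
available through the `groups` argument of `loocv_predict()`, but
leave-one-recording-out matches the original design of 80 exchangeable
values per feature set and is the default.

### HRV comparator and the combined detector

Systolic peaks are detected on the filtered signal by the two-moving-average
event detector (squared positive signal; peak window 111 ms vs beat window
667 ms plus a small offset `beta * mean(y²)`; blocks at least one peak
window wide; 250 ms refractory). Within a detected block the peak is
localized on a lightly smoothed copy (50 ms moving average), which
stabilizes the argmax against broadband noise. RMSSD is the root mean
square of successive inter-beat-interval differences, in ms, after
discarding intervals outside a 0.25–2 s physiologic gate — on a 20-s window
a single missed beat would otherwise dominate the statistic. A literal
"RMS of intervals" variant is exposed for debugging only, since one figure
caption in the source literature reads that way while the surrounding text
and universal usage mean successive differences.

The combined detector pairs one derivative feature — by default the entropy
of the 7th derivative of the filtered signal, the optimal cell reported for
the original field data — with RMSSD, under QDA LOOCV. Recordings without a
computable RMSSD are excluded; more than 20% exclusions abort the analysis.
Because the data-selected optimal cell on synthetic cohorts may differ from
the fixed default cell, `run_combined()` accepts any cell, and reports the
single-feature rules alongside the combined one.

## The synthetic cohort

`generate_cohort()` emulates the study conditions: `n_subjects` (default
40) each contribute one rest recording (BE) and one per stress stage
(E1–E3), 20 s at 367 Hz.

* **Heart rate.** Per-recording HR is drawn from truncated normals centred
  at 76 bpm at rest and 132 / 145.5 / 143 bpm for the three stages, with
  dispersions derived from the reported interquartile ranges
  (sd $\approx$ IQR/1.349: 13 and about 30–33 bpm).
* **HRV.** Beat-to-beat intervals are the base interval plus i.i.d.
  Gaussian jitter with $\sigma = \text{RMSSD}/\sqrt2$ — the simplest
  process with a closed-form RMSSD relation. No RMSSD values are printed in
  the source literature (only a boxplot contrast), so the defaults
  rest = 40 ms, stress = 15 ms were chosen once to give clear but
  overlapping separation; per-subject values vary lognormally (CV 0.25).
* **Morphology.** Each beat is a systolic Gaussian (width 0.09 s at rest,
  0.065 s under stress) plus a dicrotic Gaussian at 0.35 of the local beat
  interval (relative amplitude 0.35 at rest, 0.15 under stress). The
  heat-stress contour change is only qualitative in the literature, so
  these effect sizes are knobs, not claims. Annotated peak times are the
  local maxima of the rendered composite (the dicrotic shoulder shifts the
  maximum a few ms off the systolic centre).
* **Noise.** Baseline wander (0.2–0.4 Hz sinusoid, amplitude 0.2), 50 Hz
  powerline interference (0.02; 50 Hz reflects the data-collection region
  and is configurable), and white noise (sd 0.05), all relative to the
  per-recording pulse amplitude.

Everything is a deterministic function of the config seed.

**What the generator does not emulate:** motion artifacts, arrhythmia and
ectopic beats, respiratory amplitude modulation, sensor-specific transfer
functions, or any thermoregulatory physiology. Passing tests on this cohort
therefore demonstrate that the pipeline recovers *injected* contrasts of
the assumed structure — not that the method detects heat stress in real
recordings, and not the headline accuracies reported for the original field
data (which are not reproducible without it). On synthetic cohorts the most
discriminative cells are typically the low-order filtered ones, because
above order ~3 the cascade amplifies residual out-of-band noise, which
carries no class signal here; in real recordings the higher orders evidently
retain class structure. This divergence is expected and documented rather
than tuned away.

## Numerical and design choices

* Exact/approximate Mann–Whitney switchover at combined $n = 12$:
  enumeration is $\binom{12}{6} = 924$ assignments at worst, and the exact
  oracle tests pin correctness below the threshold. Under extreme
  discreteness (many ties at tiny $n$) the normal approximation can deviate
  from the exact p by more than 0.05; the ±0.05 agreement property is
  asserted on continuous data.
* Holm rejections use adjusted-p $\le \alpha$, equivalent to the step-down
  comparison; all-constant cells return $p = 1$.
* Ridge regularization for degenerate covariances is $10^{-6}$ of the mean
  diagonal, applied only when Cholesky fails.
* Problem sizes in the validation suite were chosen to keep the full run at
  desk scale: the end-to-end recovery checks use the full 40-subject cohort
  over 5 seeds, the type-I calibration uses 200 null cohorts of 10
  subjects, and the remaining property tests use 5–8 subjects with shallow
  cascades.

## A short example

```{r example, eval = FALSE}
cfg <- synth_config(n_subjects = 12, seed = 1)
cohort <- generate_cohort(cfg)
scan <- run_scan(cohort)
summary(scan)
plot(scan)
combined <- run_combined(cohort, features = scan$features)
combined
```

## Known limitations

* Leave-one-recording-out mixes a subject's rest and stress recordings
  across folds; accuracies are optimistic relative to leave-one-subject-out.
* The 20-s window makes RMSSD noisy (about 24 successive differences at
  rest); detector jitter adds a few ms in quadrature.
* The screening family treats the three stage comparisons as independent
  tests, as in the original analysis; they share the BE sample.
* The synthetic generator's class contrast is configurable, so absolute
  accuracies on synthetic cohorts are properties of the chosen defaults,
  not of the method.
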