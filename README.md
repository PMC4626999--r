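# ppgheat

Heat-stress detection from whole photoplethysmogram (PPG) recordings.

## What this package is for

Exertional heat stress raises heart rate and suppresses parasympathetic
heart rate variability, and both effects are visible in a fingertip PPG.
Rather than delineating individual pulse waves — which is fragile on short,
noisy recordings — this package analyses each 20-second recording as a
whole. It is aimed at physiological signal-processing researchers who want
a tested, reproducible implementation of the derivative-scan methodology,
together with a synthetic rest/heat-stress cohort generator for validating
every stage.

## The method

Each recording `S_0` (raw, and bandpass-filtered with a second-order
0.5–7 Hz Butterworth) is differentiated recursively up to order 20:

    S_i[n] = (S_{i-1}[n] - S_{i-1}[n-1]) / T,   T = 1/f_s

Every derivative order is summarized by two whole-recording functionals,

    E_j = (1/N) Σ S_j[n]²                       (normalized energy)
    P_j = -(1/N) Σ S_j[n]² ln(S_j[n]²)          (normalized Shannon entropy)

giving 84 feature cells per recording (2 features × 2 filtering statuses ×
orders 0–20). Rest (BE) vs post-exertion (E1–E3) contrasts are screened per
cell with two-sided Wilcoxon–Mann–Whitney tests under Holm–Bonferroni
correction, and every cell is benchmarked with four classifiers —
Mahalanobis distance, LDA, QDA and a linear SVM — under leave-one-out
cross-validation. A cell's overall accuracy (OA) is the mean F1 across the
four classifiers, with SE = TP/(TP+FN), PP = TP/(TP+FP) and
F1 = 2·SE·PP/(SE+PP). Finally, the chosen derivative feature is fused with
RMSSD (root mean square of successive inter-beat-interval differences, from
the package's two-moving-average systolic peak detector) in a quadratic
classifier.

Because the original field recordings are not publicly deposited, a seeded
generator (`generate_cohort()`) emulates the cohort: 40 subjects, 20 s at
367 Hz, resting heart rate centred at 76 bpm vs 132–145.5 bpm after
exertion, RMSSD 40 ms vs 15 ms, reduced dicrotic amplitude and narrower
systolic width under stress, plus baseline wander, 50 Hz powerline
interference and white noise.

## Worked example

```r
library(ppgheat)

cfg    <- synth_config(n_subjects = 12, seed = 1)
cohort <- generate_cohort(cfg)

## HRV comparator: heart rate up, RMSSD down under stress
h <- hrv_analysis(cohort)
aggregate(cbind(mean_hr_bpm, rmssd_ms) ~ condition, h,
          function(v) round(median(v), 1))
#>   condition mean_hr_bpm rmssd_ms
#> 1        BE        80.7     38.1
#> 2        E1       124.2     18.6
#> 3        E2       152.4     20.8
#> 4        E3       136.6     16.2

## Derivative-order scan
scan <- run_scan(cohort, max_order = 10)
scan
#> <ppg_scan> 44 cells x 3 comparisons, classifiers: mahalanobis, lda, qda, svm_linear
#> Optimal cell per feature/status block (mean OA across comparisons):
#>   feature     status order   OA
#> 1  energy   filtered     2 97.2
#> 2  energy unfiltered     0 62.7
#> 3 entropy   filtered     2 97.2
#> 4 entropy unfiltered     0 66.3
#> Overall optimal: energy / filtered, order 2 (OA 97.2%)

## Combined derivative-entropy + RMSSD quadratic detector
run_combined(cohort, features = scan$features, hrv = h)
#> <ppg_combined> entropy(filtered, order 7) + RMSSD under qda LOOCV
#>   BE_vs_E1: SE 91.7%  PP 78.57%  F1 84.6%
#>   BE_vs_E2: SE 66.7%  PP 61.54%  F1 64.0%
#>   BE_vs_E3: SE 91.7%  PP 73.33%  F1 81.5%
#> Mean F1: combined 76.7% | feature alone 46.7% | RMSSD alone 80.4%
```

The median detected heart rates and RMSSD values recover the generator's
rest/stress contrast; the scan finds the filtered low-order cells most
discriminative on synthetic data (high derivative orders amplify residual
broadband noise, which carries no class signal in the simulator — see the
methods vignette for why this differs from field data); and the combined
detector performs on par with the stronger of its two ingredients.

See `vignettes/heat-stress-ppg.Rmd` for the full account of the model,
parameter choices and limitations.

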