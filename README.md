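# ecgfusion

Multi-label arrhythmia classification from 12-lead ECG, combining a
118-attribute feature catalog, sparse multi-label attribute selection and a
compact CNN-GRU fusion classifier — with a synthetic multi-label ECG
generator so the whole stack runs and is testable without any clinical
download.

## Who this is for

Researchers and engineers working on physiological signal classification
who need a transparent, fully inspectable reference implementation of a
feature-based multi-label ECG pipeline: every stage (wave delineation,
feature definitions, the selection objective, the network's forward and
backward passes, the evaluation metrics) is plain R with tests against
independent oracles.

## The method

Records carry subsets of six labels: Normal, AF, PVC, PAC, LBBB, RBBB.
The pipeline is:

1. **Fiducials.** Pan–Tompkins-style R-peak detection (band-pass 5–15 Hz →
   differentiate → square → 150 ms integration → adaptive threshold,
   200 ms refractory) and window-based P/Q/S/T delineation on a
   configurable lead (default II).
2. **Attributes.** A locked catalog of 118 features per record — 27
   time-domain (RR statistics: min/max, median heart rate, RMSSD, …), 35
   frequency-domain (band powers, normalized LF/HF, spectral shape, Haar
   wavelet energies), 30 morphological (Q/R/S depths, QRS width, ST slope,
   … as mean+SD over beats) and 26 nonlinear (sample/approximate/fuzzy
   entropy, Poincaré SD1/SD2, DFA, fractal dimensions, …).
3. **Selection.** With design matrix *X* (n × d) and label matrix
   *Y* (n × m), solve

   min<sub>W</sub> ‖XW − Y‖²<sub>F</sub> + α tr(F L₁ Fᵀ) + β tr(Fᵀ L₂ F)
   + γ₁‖W‖₂,₁ + γ₂‖W‖₁,  F = XW,

   where L₁/L₂ are Laplacians of a cosine label-similarity graph and a
   KNN instance graph. Solved by monotone FISTA with an exact composite
   prox; features ranked by row ℓ₂ norms of W; top 20 kept.
4. **Classifier.** Sliding-window matrices (signal RMS + selected
   attributes per window) pass through 1-D conv blocks (kernels 20/10/5,
   filters 3/6/6) with max-pooling, a GRU (width 20), and dense layers
   20 → 10 → m with per-label sigmoids; minibatch SGD on summed per-label
   cross-entropy.
5. **Metrics.** Hamming loss, Jaccard similarity, bitwise and subset
   accuracy, micro/macro precision/recall/F1, per-label confusion tables.

The methods vignette (`vignettes/methods.Rmd`) documents every model
assumption, parameter default and open design choice.

## Worked example

```r
library(ecgfusion)

rec <- generate_record(
  list(rhythm_spec("AF"), rhythm_spec("PVC")),
  duration_s = 10, fs = 500, noise_sd = 0.02, seed = 7
)
rec
#> <ecg_record> synthetic: 12 leads x 5000 samples @ 500 Hz (10.0 s), labels {AF, PVC}, 13 beats

fid <- find_fiducials(rec, lead = "II")
head(fid, 3)
#> # A tibble: 3 x 6
#>    beat     p     q     r     s     t
#>   <int> <int> <int> <int> <int> <int>
#> 1     1    91   138   159   177   278
#> 2     2   509   585   604   622   732
#> 3     3   753   833   852   871   979

v <- extract_all(rec, fiducials = fid)
round(v[c("rr_cv", "rmssd", "qrs_width_mean", "p_amp_mean")], 3)
#>          rr_cv          rmssd qrs_width_mean     p_amp_mean
#>          0.194          0.186          0.074          0.081
```

The record is in atrial fibrillation with ventricular ectopy, and the
features show it: the RR coefficient of variation (0.194) and RMSSD
(0.186 s) are far above sinus-rhythm values (≈0.03 and ≈0.02 s), the mean
QRS width is stretched by the wide ectopic beats, and the mean P-wave
amplitude is depressed because AF beats have no P wave.

The full pipeline — simulate, detect, extract, select, train, evaluate —
is one call:

```r
report <- run_pipeline(run_config(n_records = 300, split_policy = "holdout", seed = 42))
report$metrics[, c("model", "accuracy", "hamming_loss", "jaccard", "precision", "recall", "f1")]
#> # A tibble: 2 x 7
#>   model    accuracy hamming_loss jaccard precision recall    f1
#>   <chr>       <dbl>        <dbl>   <dbl>     <dbl>  <dbl> <dbl>
#> 1 cnn_gru     0.833        0.167   0.602     0.670  0.663 0.667
#> 2 majority    0.729        0.271   0.290     0.442  0.293 0.352
```

On held-out synthetic records the trained pipeline clearly beats the
per-label majority baseline on every metric. A thin CLI wraps the same
functions: `exec/ecgfusion simulate|detect|extract|select|run-all`.

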