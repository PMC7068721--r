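# oddballerp

Simulation and analysis of infant auditory-oddball ERP studies of
habituation and novelty detection.

## The problem

In the first months of life the infant P3 — the prominent positive ERP
component around 200–450 ms at frontal sites — shifts from being driven by
stimulus *intensity* (newborns respond most to loud/broadband deviants) to
being driven by stimulus *novelty* (by ~2–5 months, never-heard sounds
elicit the largest response). The three-condition oddball paradigm measures
this shift: 800 **Frequent** pure tones, 100 **Infrequent** white-noise
deviants and 100 **Trial Unique** novel sounds per session, presented for
100 ms with 650–750 ms jittered inter-stimulus intervals while 8-channel
EEG (Fz, FC1/2, C1/z/2, CP1/2; 500 Hz; left-mastoid reference) is recorded.

Two scalar markers summarise a longitudinal session pair:

* **habituation score** = P3 mean amplitude (first half of session) −
  (second half), per condition — positive values mean the response
  decremented;
* **ΔP3** = (Infrequent − Trial Unique P3 contrast at 1 month) −
  (same contrast at 5 months) — positive values index the developmental
  shift from intensity- to novelty-driven responding. ΔP3 is then related
  to a cognitive outcome composite score, against anthropometric growth
  z-scores (WAZ/LAZ/HCZ/WLZ), via correlations and hierarchical
  regressions with R²-change tests and FDR correction.

Because no public recordings accompany the paradigm, the package includes a
full synthetic-data generator (Gaussian-bump ERP templates with exponential
habituation decay, pink/white noise, sweat drift, injected >200 µV
artifacts, cohort presets with known ground truth and an outcome score
linearly coupled to true ΔP3), so every stage of the pipeline is testable
against known truth. The package is aimed at methods developers and
students of developmental EEG who need a reproducible, fully specified
reference implementation of this analysis chain.

## What the pipeline does

1. **simulate** — `oddball_design()`, `generate_sequence()`,
   `synthesize_recording()`, `generate_cohort()`
2. **preprocess** — `preprocess_session()`: 0.5–30 Hz zero-phase Blackman
   FIR (order 5500), 32 ms marker offset correction, −200..800 ms epochs
   with baseline correction, ±200 µV / <0.1 µV rejection, trial-count
   equalization, ≥15-trials inclusion rule
3. **components** — `measure_components()`: age-specific window mean
   amplitudes and peak latencies at Fz; `jackknife_latency_test()`:
   leave-one-out latency inference with corrected statistics
   (t/(n−1), F/(n−1)²)
4. **markers** — `habituation_scores()`, `delta_p3()`
5. **stats** — `rm_anova()` (partial η²), `paired_contrast()` (Cohen's d),
   `correlate_and_compare()` (Fisher r-to-z), `hierarchical_regression()`
   (R²-change), `fdr_correct()`, `state_effect_check()`
6. **orchestration** — `run_pipeline()` + `inst/cli/erp-novelty`

## Worked example

```r
library(oddballerp)

cfg <- run_config(n_per_cohort = 6, seed = 42)
res <- run_pipeline(cfg, out_dir = "demo_out")

dplyr::group_by(res$markers, cohort) |>
  dplyr::summarise(mean_delta = mean(delta_uv), truth = mean(true_delta_p3_meas))
#> # A tibble: 2 x 3
#>   cohort mean_delta  truth
#>   <chr>       <dbl>  <dbl>
#> 1 Gambia    -0.0396  0.532
#> 2 UK         4.31    4.97
```

(A 6-subject demo takes a couple of minutes; the full 1000-trial sessions
are synthesized and preprocessed one at a time.) The UK-like cohort
recovers a clearly positive mean ΔP3 (≈ 4.3 µV on the measurement scale,
against a generator truth of ≈ 5.0 for these six subjects — the
template-unit truth of 8 µV shrinks under the window-mean/filter
measurement operator), while the Gambia-like cohort sits at ≈ 0: the
pipeline recovers the presence of a developmental shift in one cohort and
its absence in the other. `res$stats` additionally holds the Condition × Age × Cohort ANOVA
of P3 amplitude, the habituation ANOVA, per-cohort ΔP3–outcome
correlations with their Fisher comparison, and both hierarchical
regression models (`model1`, `model2`) with R²-change tests.

Plots: `autoplot()` on waveforms and jackknife results,
`plot_condition_waveforms()`, `plot_marker_association()`.

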