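---
title: "Methods: simulating and analysing infant auditory-oddball ERPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing infant auditory-oddball ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oddballerp)
```

## The paradigm and the markers

`oddballerp` implements an end-to-end pipeline for the three-condition
auditory oddball paradigm used to study habituation and novelty detection in
young infants. A session presents 1000 sounds — 800 *Frequent* pure tones,
100 *Infrequent* white-noise bursts (an intensity deviant) and 100 *Trial
Unique* novel sounds, each presented once — for 100 ms each with inter-
stimulus intervals jittered uniformly between 650 and 750 ms. EEG is
recorded from eight frontocentral electrodes (Fz, FC1/2, C1/z/2, CP1/2) at
500 Hz against a left-mastoid reference, which is retained throughout (no
re-referencing, as appropriate for a low-density montage).

The analysis quantifies event-related potential (ERP) components at Fz as
window **mean amplitudes** (more robust than peak amplitude in noisy infant
data) in age-specific windows: at 1 month an N1 (50–150 ms), P3
(250–450 ms) and Nc (550–750 ms); at 5 months a P1/N2 complex (60–80,
90–110 ms) and earlier P3 (200–400 ms) and Nc (500–700 ms) windows,
reflecting latency decreases with maturation.

Two derived markers carry the scientific content:

* **Habituation difference score** — P3 mean amplitude averaged over the
  first half of the session minus the second half, per condition. Positive
  scores mean the response decremented (habituation); near-zero scores mean
  no change.
* **ΔP3** — the Infrequent − Trial Unique P3 contrast at 1 month minus the
  same contrast at 5 months. Newborns respond more to intensity (Infrequent
  largest); by about 2–5 months a novelty response (Trial Unique largest)
  emerges. A positive ΔP3 therefore indexes the developmental shift from
  intensity- to novelty-driven responding, and is modelled against a
  cognitive outcome composite score alongside anthropometric growth
  (z-score) covariates.

Latency inference uses the **jackknife** approach: n leave-one-subject-out
grand averages are formed, the peak latency of each is measured, and the
test statistic computed on these latencies is deflated — t by (n−1), F by
(n−1)² — to undo the artificial reduction of error variance that averaging
induces; p-values come from the corrected statistic.

## The synthetic-data generator

No public recordings accompany this paradigm, so the package ships a
forward model that generates the full study from known ground truth; every
downstream stage is tested against that truth.

**Signal model.** Each ERP component is a Gaussian bump
$A_c \, e^{-(t-\mu)^2 / 2\sigma^2}$ with condition-specific signed peak
amplitude $A_c$, peak latency $\mu$ and width $\sigma$ (in ms). Gaussians
were chosen because the paradigm's analysis operators — window means,
filtering, baseline subtraction — then have closed-form or cheaply
computable expectations, enabling exact recovery tests. Habituation is
exponential: the k-th presentation of a condition is scaled by
$(1-r)^k$ with per-trial rate $r$; only first-half/second-half averages are
analysed downstream, so any monotone decay would do and the exponential is
the simplest. The single component time course is projected to the eight
channels through fixed frontocentral gains (Fz = 1.0 down to CP = 0.7).
On top of the deterministic response the generator adds:

* broadband noise, an even mix of white and 1/f (pink) noise, 20 µV RMS by
  default — awake infant EEG magnitude;
* a slow sinusoidal drift (50 µV, 10 s period) standing in for sweat-induced
  baseline wander, the artifact that motivates the 0.5 Hz high-pass;
* high-amplitude artifacts in a configurable fraction of trials (default
  35%): a 7 Hz, 400 ms burst of 500 µV peak-to-peak on one random channel.
  The burst frequency sits in the filter passband so the artifact survives
  filtering and is guaranteed to trip the ±200 µV rejection rule; the
  default fraction reproduces the retained-trial counts typical of infant
  sessions (≈55–65 of 100 oddball trials surviving).

**Cohort presets.** Two presets encode the developmental patterns the
pipeline must recover, in template peak-amplitude units:

| preset | 1 month (F/I/TU) | 5 months (F/I/TU) | true ΔP3 |
|--------|------------------|-------------------|----------|
| UK     | 4 / 9 / 5        | 4 / 5 / 9         | +8 µV    |
| Gambia | 4 / 9 / 5        | 4 / 8.5 / 4.5     | 0 µV     |

The UK-like preset crosses over from intensity- to novelty-dominance and its
Infrequent habituation rate rises from 0.002 to 0.020 per trial across age
(sized so the habituation gain across age is a medium-large subject-level
effect, matching the magnitude reported for this developmental change);
the Gambia-like preset keeps the Infrequent − Trial Unique contrast constant
across age (both oddball amplitudes decline mildly, so there is no crossover
and true ΔP3 is exactly zero) and its habituation rate stays at 0.004. The
marker-level ground truth is the point: one cohort changes, the other does
not. Between-subject variation adds N(0, 1.5 µV) to every true condition
amplitude.

Anthropometric z-scores (WAZ/LAZ/HCZ/WLZ at both ages) are drawn from a
multivariate normal with cohort-specific means, cross-measure correlation
0.45 within age, 0.7 across age for the same measure and 0.3 otherwise —
mirroring the strong mutual correlation of growth indicators that motivates
univariate predictor screening. The outcome composite score is
`outcome_mean + slope × (true ΔP3) + N(0, outcome_sd)`; the default slope is
calibrated so the population R² of the within-cohort ΔP3–outcome
association is 0.08.

**Measurement-scale ground truth.** The preprocessing chain is linear in
the embedded component, so the noise-free expectation of every reported
measure is computable: a unit Gaussian bump is pushed through the actual
designed FIR kernel (delay-compensated numerical convolution), baseline-
corrected, and averaged over the analysis window. Cohort tables carry both
the template-unit truth (`true_delta_p3`) and this measurement-scale truth
(`true_delta_p3_meas`, `true_hab_gain`); recovery tests compare pipeline
output to the latter, because the 0.5 Hz high-pass and baseline subtraction
shrink window means of in-band bumps by a few percent and a correct truth
definition must include the measurement operator.

**What the generator does not emulate.** Real acoustic content (Trial
Unique variability is metadata only — analysis never uses it), sleep-stage
microstructure (state is a label), ocular/cardiac artifacts with realistic
topographies, non-stationary noise, and volume-conduction head geometry
(channel gains are a fixed vector). Passing recovery tests therefore shows
the *analysis chain* is correct under a known forward model, not that the
forward model captures every property of infant EEG.

## Preprocessing

Following standard infant ERP practice: band-pass 0.5–30 Hz with a
zero-phase Blackman-windowed FIR of order 5500 (group delay of 2750 samples
fully compensated; DC removed; applied by FFT convolution with zero-padded
edges); event markers advanced 32 ms (the measured stimulus-delivery delay;
rounding to samples is half-away-from-zero, so 3 ms at 500 Hz is +2
samples); epochs cut from −200 to +800 ms (inclusive endpoints: 501 samples
at 500 Hz) with per-channel baseline subtraction of the pre-stimulus mean;
epochs rejected when any channel's peak-to-peak amplitude exceeds 200 µV or
falls below 0.1 µV (flatline). The any-channel veto is the strictest
reading of a per-epoch rule; a Fz-only mode is provided since analysis uses
Fz alone. Trial counts are then equalized — the condition with fewest valid
trials sets the size and the others are down-sampled by seeded sampling
without replacement, preserving presentation order — and a dataset enters
analysis only with ≥ 15 trials per condition after equalization.

Two ordering choices were genuinely open and are fixed as defaults with
alternatives available: baseline correction is on by default (harmless for
drift-free synthetic fixtures, standard for real data, toggleable); the
habituation half-split is taken per condition over *kept* (post-
equalization) epochs by presentation order, so both halves have equal
condition counts — a session-midpoint split would confound the score with
the rejection pattern. Odd counts put the middle epoch in the first half.

## Statistics

The statistical layer reproduces the paradigm's standard toolkit with base
R fitting machinery behind a tidy interface: balanced repeated-measures
mixed ANOVA via `aov()` `Error()` strata with partial eta squared from the
stratum sums of squares (uncorrected dfs by default, matching conventional
integer-df reporting; a Greenhouse–Geisser option exists for one-way within
designs); paired contrasts with Cohen's d = mean difference / SD of
differences; Pearson correlations per cohort compared through the Fisher
r-to-z transform (both one- and two-sided p reported, since reported
comparisons of correlations are sometimes one-sided); hierarchical
regressions in which candidate growth predictors are screened univariately
(lowest p enters, ties broken alphabetically, collinearity above |r| = 0.9
warned) before the ΔP3 marker is added and the R²-change tested by
incremental F; Benjamini–Hochberg FDR for the exploratory families; and a
state (asleep/awake) check that matches subjects on good-trial counts
(greedy nearest within ±5) before a Condition × State ANOVA.

## Numerical choices

* Window means use inclusive endpoints on the 2 ms grid. The inclusive-
  endpoint sample mean equals, to well under 0.01 µV, the Gaussian integral
  over the half-sample-widened window divided by its length — the analytic
  oracle used in tests.
* Peak latency is the extremum sample within the window, polarity-aware,
  ties resolved to the earliest sample; peaks landing on a window edge are
  flagged.
* The FIR is designed with `signal::fir1` (window method); the realized
  stopband attenuation at 0.05 Hz matches the designed magnitude response
  to within 1%.
* Degenerate inputs are handled explicitly: constant data give F = 0 / p =
  1, zero-variance paired differences flag an infinite t, constant
  correlation inputs are flagged undefined rather than erroring mid-
  pipeline.
* Every stochastic step takes an explicit seed (sequence, subject signal,
  equalization, cohort); fixed seeds give bit-identical output at each
  level.

## Problem sizes used in the test-suite studies

Simulation studies in the package's tests use sizes chosen to give stable
Monte-Carlo estimates on a single CPU: marker-recovery runs the full
signal-level pipeline at 40 subjects per cohort under the default
1000-trial design; jackknife power uses 200 replicates at n = 12 with a
40 ms latency shift; type-I calibration uses 1000 replicates per test at
the marker-table level (the table-level generator shares the cohort truth
machinery but skips signal synthesis, which changes nothing about the
statistics under test); the R²-change envelope uses 200 replicates at
n = 150.

The jackknife power study deserves one note: peak latency is a mode-like
estimator, and when waveform noise is appreciable relative to the curvature
at the (flat) P3 peak, discrete peak-picking — not the jackknife machinery —
limits power. The power study therefore runs at grand-average-quality
residual noise (0.2 µV, band-limited), the regime in which leave-one-out
grand averages actually live; at substantially higher noise the corrected
test remains valid but underpowered, which is a known property of peak
measures and one reason mean amplitudes are preferred for the component
analyses.

## Known limitations

* The Gaussian-bump forward model has no asymmetric components, no
  overlapping oscillatory background, and treats habituation as smooth
  exponential decay; real infant ERPs are messier in all three respects.
* Simulated between-cohort differences are amplitude patterns only; no
  attempt is made to model why cohorts differ.
* The jackknife module covers within-subject contrasts in one group;
  between-cohort latency questions are answered by running it per cohort,
  not by a pooled mixed-design correction.
* The ANOVA layer requires complete balanced within-cells, as the classic
  repeated-measures decomposition does; subjects failing inclusion at
  either age simply drop from longitudinal models.
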