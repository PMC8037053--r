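---
title: "Assessing programmer cognitive load from EEG: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing programmer cognitive load from EEG: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogload)
```

## The problem

When a programmer reads code, the mental effort spent on comprehension
leaves a spectral signature in scalp EEG: frontal midline theta power
(4–8 Hz) rises and parietal alpha power (8–13 Hz) falls as cognitive load
increases. `cogload` implements a complete analysis pipeline around that
signature:

1. classify, from EEG alone, which of several code-comprehension tasks of
   different complexity a subject is performing (against a
   natural-language reading control), and
2. localize, in screen space and time, the specific code regions that
   drive load peaks, by fusing EEG load indices with eye-tracking data.

Because the pipeline is developed and tested without access to human
recordings, the package ships a first-class synthetic cohort generator
that reproduces the statistical structure the analysis relies on. The
generator is study apparatus, not a test fixture: its defaults *are* the
study conditions.

## Study protocol and the synthetic cohort

Each subject performs three trials. A trial is the fixed sequence

> fixation cross (30 s) → reading control (≤ 60 s) → fixation cross
> (30 s) → code comprehension (≤ 10 min),

with code tasks ordered C1 → C2 → C3 by nominal (metric-based)
complexity. The crosses provide neutral-load baselines for the task that
follows them. After each trial the subject reports mental effort on a
1–6 NASA-TLX scale.

`cohort_config()` encodes these conditions. The EEG signal model is a sum
of independent band-limited Gaussian noise processes, one per canonical
band (Delta 0–4, Theta 4–8, Alpha 8–13, Beta 13–30 Hz, and the three
gamma sub-bands 30–50/50–70/70–90 Hz), over a pink-noise floor. Only the
*amplitudes* of these processes carry information: per unit of task load,
theta amplitude is multiplied by 1.35 and alpha by 0.80 at the
fronto-parietal target electrodes (Fz, F2, FCz, Pz, CPz, CP2; other
channels get 20% of the modulation). This is deliberate minimalism — the
feature set downstream is purely spectral, so simulating waveform
morphology (ERPs, connectivity) would add realism the analysis cannot
see. Passing tests on this generator therefore demonstrate that the
pipeline recovers *band-power structure*; they say nothing about
artifacts, non-stationarity, or morphology effects in real data.

Default parameter choices, made once:

* **Task loads** 1.0 / 2.3 / 2.3 for C1/C2/C3 and 0.25 for reading. The
  equal C2/C3 loads encode the mental-effort *saturation* between the two
  harder tasks that motivates the merged C2/C3 class; NASA-TLX scores are
  generated as `1 + 1.8·load + N(0, 0.45)` clipped to [1, 6], with C2 and
  C3 drawing from the same distribution.
* **Band RMS amplitudes** (µV): Delta 8, Theta 6, Alpha 10, Beta 4,
  gammas 1.5/1.0/0.8, pink floor 5 — ordinary resting-EEG proportions.
* **Between-subject variability**: a log-normal global gain (σ = 0.15)
  and per-event load jitter (σ = 0.08).
* **Gaze**: dwell-based sampling at 60 Hz; a dwell picks a code line with
  probability proportional to its area, critical lines weighted by
  `dwell_bias` (default 3). With `critical_boost > 0`, theta load is
  additionally raised while the gaze dwells inside a critical region —
  the space-time coupling the fusion analysis is designed to detect.
* Optional artifact injection (50 Hz line, blink-like frontal
  transients) is off by default; it exists to give the preprocessing
  stage something to remove in its own tests.

All randomness flows from one integer seed; identical configuration and
seed give bit-identical cohorts.

## Preprocessing

`apply_filters()` → `detect_bad_channels()` / `interpolate_channels()` →
`rereference_average()` → `reject_gross_segments()` → `fit_ica()` →
`flag_artifact_components()` → `remove_components()`, with the order
enforced through the recording's history.

Choices worth knowing:

* Filters are Hamming-window FIR designs (high-pass 1 Hz, low-pass
  90 Hz, notch 48–52 Hz) applied **zero-phase**, so the windowed features
  downstream suffer no group delay. Transition bandwidths follow the
  standard 3.3/N Hamming heuristic and are recorded in the history.
* Bad channels are found automatically (variance below a flat threshold,
  or robust log-variance z-score above a threshold) rather than by visual
  inspection, and are replaced by spherical-spline estimates (stiffness
  m = 4, 20 Legendre terms, ridge 1e-5) from the remaining channels'
  idealized 10-10 unit-sphere positions.
* The average reference makes the data rank-deficient by one;
  `fit_ica()` therefore whitens to the numerical rank and fits
  channels − 1 components by default. The ICA is extended-Infomax:
  natural-gradient block updates with per-component sub/super-Gaussian
  signs re-estimated from activation kurtosis, annealed learning rate,
  deterministic under a fixed seed.
* Artifact components are flagged by three scores replacing manual
  inspection — frontal topography dominance × low-frequency power ratio
  (blinks), 50 Hz peak prominence (line noise), positive spectral slope
  above 30 Hz (muscle). Thresholds are arguments with conservative
  defaults; `keep_all_components` in the pipeline config disables removal
  for A/B comparisons.

## Feature engineering

A 1-second window advanced in 0.2 s steps (80% overlap) slides over every
event. Per window and channel: 8 time-domain features (raw and min–max
normalized means, variance, skewness, kurtosis, and the Hjorth
parameters) and 40 frequency-domain features (total power; absolute and
relative power of the 7 bands; all 21 pairwise band ratios; the two
engagement indexes β/(θ+α) and θ/(β+α); the PSD centroid; the alpha peak
frequency). Across channels: differential and rational asymmetries for 9
homologous left–right pairs × 7 bands, plus the frontal–parietal
"Brainbeat" index θ(Fz)/α(Pz). On the 60-channel montage this is
480 + 2400 + 127 = **3007** named features per window.

Conventions that the printed counts force or the literature leaves open,
decided as follows:

* Hjorth *activity* duplicates the variance column by design; emitting
  both keeps the per-channel count at 8.
* "Mean of the normalized signal" uses min–max scaling within the window
  (z-scoring would make the feature identically zero).
* Skewness/kurtosis are biased moment estimators; kurtosis is raw
  (non-excess), so Gaussian windows sit near 3.
* Hjorth derivatives are first differences scaled by the sampling rate:
  a pure sinusoid of frequency f has mobility 2πf rad/s and complexity 1,
  which the tests assert at 1%.
* The PSD is a single-window periodogram (squared FFT magnitude),
  one-sided, normalized so the non-DC bins sum to the biased variance
  (Parseval); at the 1 s window the resolution is exactly 1 Hz.
* Bands are half-open [low, high) and the three gamma sub-bands replace
  any aggregate gamma column — this makes the 7 bands partition [0, 90)
  (relative powers sum to 1) and the per-channel frequency count exactly
  40.
* The 9 asymmetry pairs default to Fp1/Fp2, F7/F8, F3/F4, FC3/FC4,
  C3/C4, CP3/CP4, P3/P4, P7/P8, O1/O2 (configurable); 9 × 7 × 2 + 1
  gives the 127 multi-channel features.
* Every ratio denominator is guarded at 1e-12 × total power; the alpha
  peak tie-break is the lowest maximal bin; zero-variance windows return
  flagged zeros. All features are finite for arbitrary input.

## Baseline normalization, segmentation, sample tables

Task windows are converted to relative variations against the fixation
cross immediately preceding the task in the same trial:
Δ = (value − baseline mean)/baseline mean. Baselines smaller in magnitude
than 1e-9 × the feature's typical baseline scale would make Δ explode;
such cells are set to 0 and flagged (near-zero baselines are legitimate
for asymmetry features).

Each task is then split into 4 contiguous segments by window count
(remainder to the earliest segments — equivalent to wall-time splitting
at a fixed hop and robust to rejected windows), and each segment is
summarized by 5 second-order statistics per feature — maximum, minimum,
mean, standard deviation (sample, n−1), median — giving 15035 values per
segment. Two tables result: the **binary** table (per-trial controls
kept separate: subjects × 6 tasks × 4 segments, 624 rows at 26 subjects)
and the **multiclass** table (controls of all trials concatenated in time
order and re-split into 4 segments: subjects × 4 × 4 = 416 rows).
`relabel_nasa()` merges C2 and C3 into one class when their cohort-mean
NASA-TLX scores agree within a saturation gap (default 1 point on the
6-point scale), exposing the relabeling as an explicit rule rather than a
hidden threshold.

## Selection, classification, evaluation

Feature scaling (z-score), selection/reduction and classifier fitting all
happen **inside each training fold** of the leave-one-subject-out loop —
the stricter no-leakage convention; fitting the scaler on all subjects
first is the other common reading of standard practice, and the
difference can matter at these sample sizes. Hyperparameters, when a grid
is given, are chosen by a nested LOSO over the training subjects.

Selectors: Kruskal–Wallis (multiclass) or Mann–Whitney (binary) ranking
with greedy Pearson pruning (default |r| > 0.95 drops the lower-ranked
feature); ReliefF (all instances, range-normalized Manhattan metric);
greedy normalized-mutual-information selection (equal-width 10-bin
discretization, √(H·H) normalization, relevance minus mean redundancy
with near-duplicates excluded); PCA by cumulative explained variance
(Gram-matrix eigendecomposition when p ≫ n). The column-wise rank
statistics are vectorized re-implementations cross-checked in the tests
against `kruskal.test`/`wilcox.test`, and the package's Mann–Whitney is
additionally checked against exhaustive enumeration at small n.

Classifiers: linear SVM and Gaussian Naive Bayes (via `e1071`), kNN (via
`class`), and an in-package Fisher LDA with shrinkage-regularized pooled
scatter (singular scatter is inevitable at p ≫ n), one-vs-one with
margin-based tie-breaking for multiclass. Metrics are per-class
one-vs-rest recall, precision, specificity and F-measure plus accuracy,
reported as mean ± SD over folds; `compare_models()` runs pairwise
two-sided Mann–Whitney tests on per-fold accuracies with Bonferroni
correction. `top_feature_summary()` aggregates each fold's top-k ranked
features into per-electrode and per-feature-type percentages (asymmetry
features count toward both electrodes).

## Space-time fusion

`feature_timecourse()` tracks two discriminant load indices —
θ/(β+α) at F2 and θ/α at Pz — per window, baseline-normalized like the
feature matrix. Gaze points are clustered by DBSCAN in the 3-D space
(time, y-coordinate, consecutive-point distance); the three dimensions
are z-scored first because their raw units are incommensurable (defaults
eps 0.5, minPts 10). Each EEG window is assigned inside/outside the
critical AOIs by the majority of its time-overlapping gaze points;
windows without gaze are excluded (off-screen time carries no spatial
information). Normality of the two groups is checked with Shapiro–Wilk
(our choice; any omnibus test would do); if either group is non-normal
the groups are compared with a two-sided Mann–Whitney U test, otherwise
with a Welch t-test, at α = 0.05. Overlapping AOIs resolve to the
smallest containing region, and "common critical areas" are the regions
marked by all annotators.

## Problem sizes and what the checks show

The packaged tests and the acceptance script exercise the full pipeline
on a 26-subject cohort with the protocol structure intact but task
durations reduced (cross 4 s, reading 6 s, code 8 s at 200 Hz) — chosen
so a complete run takes minutes on one core. Every count identity
(3007/15035 features, 624/416 rows) is invariant to durations. Under the
default load modulation the pipeline reaches > 80% LOSO accuracy for
{C1, C2/C3, Control} with PCA + linear SVM, the four-class
Kruskal–Wallis ranking concentrates its top-100 features on the
modulated fronto-parietal electrodes and on theta/alpha/beta-derived
feature types, and the critical-region test rejects its null on subjects
with injected critical-AOI load while keeping a ~5% type-I error rate on
null simulations. The end-to-end cohort analysis in the acceptance
script skips the ICA stage: the generator's default output is
artifact-free, and preprocessing is exercised separately by its own unit
and artifact-injection tests (enable `preprocess` in `pipeline_config()`
to run it in the driver).

## Known limitations

* The generator does not emulate ERPs, connectivity, non-stationary
  artifacts, or realistic eye-tracker noise (uniform jitter only);
  results on it bound what the pipeline can do on clean band-power
  structure, not on raw lab data.
* The montage positions are an idealized spherical 10-10 layout, adequate
  for interpolation and pairing but not for source analysis.
* Exact replication of results on the original human dataset would
  additionally require the authors' unstated hyperparameter grids,
  pruning thresholds and CEV level; these are exposed as configuration
  with the defaults documented above.
* The per-component ICA flagging thresholds cannot be calibrated against
  a ground truth of manually removed components; they are deliberately
  conservative.
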