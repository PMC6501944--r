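---
title: "Decoding the three canonical BCI paradigms: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding the three canonical BCI paradigms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegbci)
```

## Scope

`eegbci` implements offline and simulated-online decoding for the three
canonical EEG brain-computer-interface paradigms — binary motor imagery
(MI), the 6x6 row-column ERP speller, and four-class SSVEP frequency
recognition — together with the neurophysiological summaries used to
inspect them (ERD/ERS, signed r², Welch spectra, resting alpha power), a
BCI-illiteracy report over accuracy tables, an HDF5 recording container,
and a seeded synthetic-EEG generator that makes every pipeline testable end
to end without any recorded data. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic data
can and cannot show.

## The recording container

Recordings are stored continuous-with-markers, one HDF5 group per
experimental phase, with the field names `x` (samples x channels), `t`
(marker onsets in samples), `fs`, `y_dec` / `y_logic` / `y_class` (labels
in integer, one-hot and name form) and `chan`. Because MAT v7.3 files are
HDF5 underneath, any container with this group layout is readable; older
binary MAT dialects and other EEG formats (EDF, BrainVision) are out of
scope. Epoching is always explicit (`segment_epochs()`), never implicit in
I/O.

The packaged montage (`montage_table()`) holds 62 EEG labels of the
extended 10-20 system plus 4 EMG channels, with approximate 2-d scalp
coordinates. Three analysis subsets are shipped verbatim
(`montage_preset()`): 32 channels for ERP, 20 sensorimotor channels (FC/C/CP
rows) for MI, and 10 occipito-parietal channels for SSVEP. EMG channels are
flagged by kind and never enter EEG computations silently.

## Shared preprocessing

All pipelines share four steps, each an explicit function:

* **Band-pass** (`bandpass_filter()`): 5th-order Butterworth, 0.5–40 Hz for
  ERP and 8–30 Hz for MI. Offline filtering is zero-phase
  (forward–backward, which squares the magnitude response) so that grand
  averages have no phase lag; the simulated online loop filters its sliding
  buffer with a causal single pass, as a real-time system must. End effects
  are suppressed by odd-reflection padding roughly three periods of the low
  band edge long.
* **Decimation** (`downsample()`): all analysis runs at 100 Hz. An 8th-order
  anti-alias low-pass at 0.8x the target Nyquist precedes decimation;
  markers are remapped by the integer ratio with floor, so a marker moves at
  most one decimated sample backwards.
* **Epoching** (`segment_epochs()`): half-open `[start, end)` windows with
  0-based sample offsets. This convention makes the standard epoch lengths
  exact at 100 Hz: 100 samples for `[-200, 800)` ms (ERP), 250 for
  `[1000, 3500)` ms (MI), 400 for `[0, 4000)` ms (SSVEP).
* **Baseline correction** (`baseline_correct()`): per trial and channel,
  subtracting the mean over `[-200, 0)` ms; idempotent by construction.

Whether one filters before or after decimation is not fixed by convention;
the pipeline filters first (`run_pipeline()`), and both orders are
available by composing the functions directly.

## Motor imagery

CSP solves \(\Sigma_1 w = \lambda(\Sigma_1+\Sigma_2)w\) on class-average
covariances. Covariances are per-trial sample covariances, trace-normalized
before averaging — the standard guard against amplitude outliers. Trace
normalization sacrifices exact invariance to channel mixing; `fit_csp(...,
normalize = "none")` restores the textbook invariant when needed (the test
suite checks both). The eigenproblem is solved by whitening the composite
covariance and diagonalizing the whitened class-1 covariance; a ridge of
1e-8 x trace is added when the composite covariance is rank-deficient.
Features are unnormalized `log(var)` of the top/bottom-`m` projections
(default m = 2, i.e. 4 features); LDA absorbs affine scaling, so
normalization would be redundant.

The variants:

* **CSSP** augments the channels with a τ-delayed copy (τ from a 1–10
  sample grid by 5-fold cross-validated accuracy, deterministic folds, ties
  to the smallest delay), giving each spatial filter an embedded two-tap
  spectral response.
* **FBCSP** runs CSP per band over nine 4 Hz bands spanning 4–40 Hz
  (order-4 filters; at 100 Hz an order-5 design is numerically fragile for
  the narrowest bands), and keeps k = 4 features by mutual information with
  the label, estimated on a 4-bin equal-frequency discretization.
* The **particle-based band search** (BSSFO-style) is deliberately a
  simplified importance-sampling scheme: 30 particles of (lo, hi) band
  edges initialized uniform on 4–40 Hz, scored by 4-fold CSP+LDA accuracy,
  resampled with softmax weights (temperature 0.05) and 1 Hz Gaussian
  jitter for 10 iterations; degenerate particles (width < 1 Hz) are redrawn
  from the prior. It is fully reproducible under a seed and is not a
  faithful reimplementation of the reference MCMC sampler.

Offline benchmarking uses 10 repetitions of stratified 10-fold
cross-validation with *all* fitting inside training folds
(`crossvalidate_mi()`). The simulated online loop (`online_decode_mi()`)
replays a 1.5 s buffer every 0.5 s — causal filter, trained projection,
LDA — and maps decision values to a feedback coordinate with
`tanh(dv / sd(dv_train))`; the squashing scale is the training
decision-value spread, a choice made here since only "transformed into
coordinates" is conventionally specified.

## ERP speller

One selection presents 5 sequences x 12 flashes (6 rows + 6 columns) at
215 ms stimulus-onset asynchrony (80 ms stimulus + 135 ms gap). Features
are mean amplitudes in 10 discriminant 50 ms windows found by sliding a
window in 10 ms steps over `[0, 800)` ms, scoring each position by the
channel-maximum |signed r²| of the window-mean amplitude, and greedily
keeping the top 10 non-overlapping positions — deterministic given the
data. How the original analysis chose its 10 intervals is unpublished, so
per-subject reproduction on recorded data cannot be bit-exact. With the
32-channel montage this yields 320 features; LDA uses Ledoit–Wolf analytic
shrinkage by default because a 320-dimensional pooled covariance from a few
thousand trials is unstable (plain LDA remains available).

Selections accumulate per-flash classifier scores: each cell averages the
scores of the flashes containing it over the first `n_seq` sequences and
the argmax cell wins (ties to the lowest row, then column — in practice
unreachable with float scores). Under a linear classifier this equals
classifying sequence-averaged epochs; score averaging is implemented
because it also works flash-by-flash online. Accuracy is reported for 1–5
accumulated sequences, and the information transfer rate uses the Wolpaw
formula with `M` from stimulation timing only: `n_seq` x 12 x 0.215 s plus
the 0.8 s epoch tail of the final flash (13.7 s per selection at five
sequences, giving the 22.6 bits/min ceiling at perfect accuracy);
gaze-shifting pauses are excluded. The 0.8 s tail is an inference from the
epoch definition — it is required to make the printed ceiling come out —
and is stated here as such.

## SSVEP

Frequency recognition is calibration-free canonical correlation against
per-frequency references \([\sin 2\pi f t; \cos 2\pi f t; \sin 4\pi f t;
\cos 4\pi f t]\) with \(t = 1/S, \dots, T/S\) — fundamental plus exactly
the second harmonic (higher harmonics are a config extension, off by
default). Both the epoch and the reference rows are mean-centered: the
references are only asymptotically zero-mean at finite length. The largest
canonical correlation is computed by thin QR of both centered data blocks
and an SVD of \(Q_X^\top Q_Y\), dropping negligible QR directions instead
of inverting covariances; ties in the argmax over frequencies go to the
first-listed (highest) frequency. A trial is classified to the frequency
with the largest correlation.

## Neurophysiological summaries

* **ERD/ERS**: band-pass (8–12 Hz default), squared amplitude,
  trial-average, 100 ms centered moving mean, then percent change against
  the mean power in a `[-500, 0)` ms reference window. With a scalar
  reference power, the curve's *mean* over the reference window is zero by
  construction (a pointwise zero would require a time-resolved baseline,
  which is not the standard definition). Squared band-passed amplitude was
  chosen over Hilbert envelopes; both agree after the 100 ms smoother at
  these bandwidths.
* **signed r²**: per channel and sample, sign(r)·r² of the point-biserial
  correlation between amplitude and class.
* **Welch PSD**: 1 s Hann windows, 50% overlap, density scaling (integrated
  PSD recovers variance); segments shorter than a window fall back to a
  single periodogram with a warning. Default display range 1–25 Hz.
* **Resting alpha power**: 10·log10 of mean PSD over 8–12 Hz per channel.

## BCI-illiteracy report

Thresholds are 70% (MI, judged on plain-CSP accuracy) and 90% (ERP, SSVEP).
Two conventions matter and are fixed here: an accuracy exactly at the
threshold counts as literate (≥), and paradigm literacy for *categories*
requires meeting the threshold in every session, while per-session
illiteracy *rates* are computed within each session and additionally
averaged across sessions. Categories — universally literate (all three
paradigms), partially literate (one or two), universally illiterate (none) —
always partition the subjects.

## The synthetic generator

`sim_config()` fixes one seed for everything. Defaults keep the recorded
study conditions: 1,000 Hz, the 62-channel montage, 100 balanced MI trials
(3 s fixation, 4 s task, 6 ± 1.5 s blank; the blank jitter is drawn
uniformly, the distribution being unrecorded), speller flashes at 215 ms
SOA with 5 sequences per character and a 4.5 s inter-character pause, and
SSVEP stimulation of 4 s with 6 s inter-stimulus interval, 25 trials per
class at 12/8.57/6.67/5.45 Hz.

The forward model maps sources to channels through a Gaussian spatial
kernel over the montage's 2-d coordinates (width 0.4 coordinate units) —
enough to give CSP and CCA realistic cross-channel correlation, with no
claim of anatomical realism. Background noise is spatially mixed pink (1/f)
noise at 8 µV plus a 1 µV white floor, putting resting alpha-range power
near physiological magnitude; all quantitative tests use relative
quantities, so the absolute calibration carries no claims. Paradigm
signals: MI superimposes 10 Hz mu sources at C3/C4 whose amplitude drops by
√(1−d) during the task contralateral to the cued hand (d is the
ground-truth ERD depth, default 0.8); ERP adds a positive centro-parietal
Gaussian bump (5 µV, 350 ± 20 ms latency, 60 ms width) to every target
flash, with overlapping responses summing linearly; SSVEP adds f, 2f, 3f
sinusoids (amplitude ratios 1 : 0.5 : 0.25) around Oz during stimulation.
Artifact segments reproduce the five stereotyped kinds (blink, horizontal
and vertical eye movements, teeth clenching, arm flexing) with their gross
spectral/topographic signatures.

What the generator does *not* emulate: non-stationary background rhythms,
inter-subject variability, volume-conduction physics, eye/muscle artifacts
inside task recordings, latency drift over a session. Passing tests
therefore demonstrate that the algorithms recover the structure they are
designed for at realistic SNR — not that recorded-data accuracies would be
reproduced. Recorded headline numbers (mean accuracies near 71/97/95% and
illiteracy rates near 54/11/10%) require the full recorded dataset, which
is far beyond desk scale; they are documented here for orientation only
and are not asserted by any test.

## Problem sizes used by tests

Tests and the acceptance script run the generators at reduced size — 500 Hz
sampling (decimated to the common 100 Hz, keeping the integer ratio), the
paradigm-specific montage subsets instead of all 62 channels, and
compressed inter-trial gaps — while keeping the decisive conditions (trial
counts such as 200 MI trials, ERD depths 0 and 0.8, full sentences for the
protocol counts, 4 s SSVEP epochs). These sizes are the package's own
choices for quick, deterministic verification; the generator defaults
remain the full study conditions.

## Numerical choices, in one place

* CSP: ridge 1e-8·trace on rank-deficient composite covariance; eigenvalues
  clipped to [0, 1]; per-trial trace normalization (see above).
* LDA: shrinkage toward the average-eigenvalue sphere; "auto" = Ledoit–Wolf.
* CCA: QR/SVD, rank decided by the QR pivot tolerance; correlations clipped
  to [0, 1]; zero-variance epochs return 0 with a warning.
* Log-variance: zero-variance projections floored at machine epsilon with a
  warning.
* Filters: Butterworth designs from the `signal` package; odd-reflection
  padding for zero-phase passes; order 4 in the FBCSP bank and the particle
  search (stability of narrow bands at 100 Hz), order 5 elsewhere.
* Speller ties: lowest (row, column); SSVEP ties: first-listed frequency;
  CSSP delay ties: smallest delay. All deterministic.
* Pink noise: spectral shaping with the FFT length padded to a
  2-3-5-smooth size.

## A worked example

```{r example, eval = FALSE}
cfg_tr <- sim_config(seed = 1, fs = 500, channels = montage_preset("MI20"),
                     mi = list(n_trials = 100, fixation_s = 1, blank_s = 1))
cfg_te <- sim_config(seed = 2, fs = 500, channels = montage_preset("MI20"),
                     mi = list(n_trials = 100, fixation_s = 1, blank_s = 1))
res <- run_pipeline(run_config("mi",
                               train = simulate_mi(cfg_tr),
                               test = simulate_mi(cfg_te),
                               method = "csp", seed = 1))
res$report
autoplot(erd_ers(segment_epochs(downsample(simulate_mi(cfg_tr)$rec, 100),
                                simulate_mi(cfg_tr)$labels, c(-1000, 4000)),
                 channels = c("C3", "C4")))
```

## Known limitations

* The particle-based band optimizer approximates, and does not reproduce,
  the reference Bayesian sampler.
* Artifact simulation covers gross signatures only; it is unsuitable for
  benchmarking artifact-removal methods.
* The montage's 2-d coordinates are schematic; topography export is
  per-channel values keyed by label, with interpolation/rendering left to
  external tools.
* Random-set flash presentation on recorded data requires the recording's
  own flash-group table; the reader reconstructs it from container
  metadata, and the synthetic protocol uses seeded permutations of the 12
  row/column groups.
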