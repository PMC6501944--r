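# eegbci

Decoding pipelines for the three canonical EEG brain-computer-interface
(BCI) paradigms, for researchers who want a compact, fully scripted
reference implementation of the standard analysis chain and a seeded
synthetic-EEG generator to exercise it end to end:

* **Motor imagery (MI)** — binary left/right-hand imagery decoded with
  common spatial patterns (CSP) and its spatio-spectral variants (CSSP,
  FBCSP, a particle-based spectral band optimizer), log-variance features
  and LDA; repeated stratified cross-validation and a simulated online
  sliding-window decoder.
* **ERP speller** — a 6x6 row-column speller decoded from mean-amplitude
  features in 10 data-driven discriminant time windows with shrinkage LDA,
  sequence accumulation to characters, and information transfer rates.
* **SSVEP** — calibration-free frequency recognition by canonical
  correlation analysis (CCA) against sin/cos references with second
  harmonics at 12, 8.57, 6.67 and 5.45 Hz.

Around the decoders: Butterworth band-pass filtering, decimation to a
common 100 Hz analysis rate, half-open epoching, baseline correction and
standard montage subsets (32 ERP / 20 sensorimotor / 10 occipital
channels); ERD/ERS band-power curves, signed r² discriminability maps,
Welch spectra and resting alpha power; a BCI-illiteracy report over
accuracy tables; and an HDF5 recording container compatible with MAT v7.3
struct layouts (`x`, `t`, `fs`, `y_dec`, `y_logic`, `y_class`, `chan`).

## The models in brief

CSP solves the generalized eigenproblem
`Σ₁ w = λ (Σ₁ + Σ₂) w`
on class-average covariances; the top/bottom-m eigenvectors give spatial
filters whose log-variance features feed LDA
(`w ∝ Σ⁻¹(μ₂ − μ₁)`, optional Ledoit-Wolf shrinkage).
SSVEP trials are classified to `argmax_i ρ(X, Y_i)`, the largest canonical
correlation between the multichannel epoch X and the reference
`Y_i = [sin 2πf_i t; cos 2πf_i t; sin 4πf_i t; cos 4πf_i t]`,
`t = 1/S … T/S`. Speller throughput is the Wolpaw information transfer
rate

```
ITR = M { log₂N + P log₂P + (1 − P) log₂((1 − P)/(N − 1)) }   [bits/min]
```

with N = 36 symbols and M from stimulation timing alone (five 12-flash
sequences at 215 ms SOA plus the 800 ms epoch tail: 13.7 s per selection).
BCI illiteracy is judged at 70% accuracy for MI (plain CSP) and 90% for
ERP/SSVEP; subjects are universally literate, partially literate or
universally illiterate according to how many paradigms meet the threshold
in all sessions.

## Worked example

Simulate a motor-imagery session, train on one phase, test on another:

```r
library(eegbci)

mk <- function(seed) {
  simulate_mi(sim_config(seed = seed, fs = 500,
                         channels = montage_preset("MI20"),
                         mi = list(n_trials = 100, fixation_s = 1,
                                   blank_s = 1, blank_jitter_s = 0.5)))
}
res <- run_pipeline(run_config("mi", train = mk(1), test = mk(2),
                               method = "csp", seed = 1))
res$report
#> # A tibble: 1 × 3
#>   method accuracy n_test
#>   <chr>     <dbl>  <int>
#> 1 csp           1    100
```

The generator plants a ground-truth event-related desynchronization of
depth 0.8 (an 80% mu-power drop contralateral to the cued hand), so the
decoder's 100% test accuracy says the CSP+LDA chain recovers exactly the
structure it is built for; at depth 0 the same pipeline sits at chance.
The ERP pipeline reports accuracy and ITR for 1–5 accumulated sequences —
at perfect accuracy the 5-sequence ITR is `22.6` bits/min — and the SSVEP
pipeline reports calibration-free CCA accuracy with a confusion matrix.

A thin command-line wrapper ships in `inst/cli/eegbci`
(`simulate`, `mi`, `erp`, `ssvep`, `illiteracy` subcommands).

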