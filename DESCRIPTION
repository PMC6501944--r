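Package: eegbci
Title: Decoding Pipelines for the Three Canonical EEG Brain-Computer Interface Paradigms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline and simulated-online decoding for the three canonical
    EEG brain-computer interface (BCI) paradigms: binary motor imagery via
    common spatial patterns (CSP) and its spatio-spectral variants (CSSP,
    FBCSP, a particle-based spectral band optimizer) with shrinkage linear
    discriminant analysis; a 6x6 row-column event-related potential (ERP)
    speller with discriminant-interval mean-amplitude features, sequence
    accumulation and information transfer rate; and steady-state visually
    evoked potential (SSVEP) frequency recognition by canonical correlation
    analysis against sinusoidal references with second harmonics. Includes
    shared preprocessing (Butterworth filtering, decimation, epoching,
    baseline correction, montage subsets), neurophysiological summaries
    (ERD/ERS band power, signed r-squared discriminability, Welch spectra,
    resting alpha power), a BCI-illiteracy report over accuracy tables, an
    HDF5 recording container compatible with MAT v7.3 struct layouts, and a
    seeded synthetic-EEG generator that emulates all three paradigms plus
    artifact segments so every pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    rhdf5,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
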