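Package: eegtraits
Title: Resting-State EEG Oscillatory Traits and Visual-Exploration Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline linking spontaneous EEG
    oscillatory features to visual-exploration phenotypes. Provides a
    ground-truth synthetic cohort generator (fractional Gaussian noise
    drivers, 1/f background, narrowband oscillations, gaze traces),
    deterministic EEG preprocessing (zero-phase FIR filtering, resampling,
    bad-channel detection, spherical-spline interpolation, average
    reference), Welch spectral analysis with relative band power and
    individual alpha frequency detection, detrended fluctuation analysis
    of alpha-band amplitude envelopes and binary fixation series, and the
    permutation inference layer (permutation ANOVA/t-tests, cluster-based
    permutation statistics on scalp maps, Spearman follow-ups with FDR
    correction), orchestrated into one reproducible study run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
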