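Package: eegmicrostates
Title: Resting-State EEG Microstate and Spectral Power Analysis
Version: 0.1.0
Authors@R: person("FReJA", "Analyst", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for resting-state electroencephalography
    (EEG) biomarker analysis: Kaiser-window FIR filtering, epoching,
    average referencing and spherical-spline channel interpolation;
    Welch relative band power; polarity-invariant modified K-means
    microstate segmentation with global-field-power peak selection,
    back-fitting, short-segment rejection and duration / occurrence /
    coverage / global-explained-variance statistics; exact and
    covariate-adjusted group comparisons; and a semi-Markov synthetic
    EEG generator with known microstate structure for validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
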