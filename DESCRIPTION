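Package: ecgbeats
Title: Synthetic Two-Lead ECG Generation and Four-Class Ischemic Heartbeat
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for four-class heartbeat
    classification in two-lead electrograms: non-ischemic sinus beats,
    moderate and severe ischemic beats, and ventricular premature beats.
    Provides a parametric two-lead beat/record generator with ground-truth
    fiducials (QRS onset, R peak, J point, T end); baseline-wander removal
    with a zero-phase comb filter, wavelet-based QRS detection and fixed
    280 ms segmentation; four feature families (delineation-based and
    R-peak-based morphological features; FFT/STFT/CWT/Wigner-Ville spectral
    features); filter-method feature selection (Shapiro-Wilk,
    Kruskal-Wallis with Tukey-Kramer all-pairs post-hoc); and a 10-fold
    cross-validated benchmark of nine classifier configurations
    (discriminant analysis, naive Bayes, support vector machines,
    k-nearest neighbours) with per-fold standardization and
    accuracy/sensitivity/specificity reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
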