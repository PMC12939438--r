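Package: edahrv
Title: Electrodermal and Heart-Rate-Variability Biomarkers of Cancer Pain
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Feature extraction and nonparametric group comparison for
    resting-state autonomic biosignals recorded in cancer-pain cohorts.
    Electrodermal activity is decomposed into tonic and phasic components by
    continuous decomposition analysis (nonnegative deconvolution with a
    Bateman impulse response) and by trough-to-peak scoring, yielding
    fourteen skin-conductance-response features per patient. Heart rate
    variability is derived from single-lead ECG via a Pan-Tompkins style
    QRS detector, with time-domain (SDNN, RMSSD, mean HR) and Welch
    spectral (VLF/LF/HF power, LF/HF ratio) features. Features are compared
    across pain-intensity and pain-type groups with Kruskal-Wallis tests,
    Dunn's post hoc pairwise comparisons, and Benjamini-Hochberg
    adjustment, overall and within clinical strata. A seeded synthetic
    cohort generator with known ground truth makes every stage testable
    without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
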