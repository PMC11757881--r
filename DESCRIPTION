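Package: pdcnet
Title: Partial Directed Coherence Networks from Multichannel EEG with SVM Cohort Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates effective (directed) brain connectivity from resting-state
    multichannel EEG by fitting multivariate autoregressive (MVAR) models to short
    segments and computing partial directed coherence (PDC) adjacency matrices over
    a 64-band frequency grid. Provides an MVAR-driven synthetic cohort generator
    with known ground-truth connectivity, EEG preprocessing (resampling, band-pass
    and notch filtering, segmentation), per-connectivity ANOVA feature selection
    grouped by brain rhythm, and support vector machine classification of two
    cohorts with repeated cross-validation, ROC/AUC and confusion-matrix reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    withr,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
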