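Package: physioscreen
Title: Simulation, Feature Extraction and Nonparametric Screening of
    Multimodal Stress Biosignals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how photoplethysmography (PPG),
    electrodermal activity (EDA) and skin temperature respond to stress
    and mental workload. Provides a seeded simulator for multimodal
    physiological cohorts with known class-dependent effects; zero-phase
    acquisition filtering and phase/window segmentation; beat detection
    and a 43-feature catalogue covering pulse morphology, heart-rate and
    heart-rate-variability spectral indices (PLF/PHF bands of the BPM
    trend), convex tonic/phasic EDA decomposition with skin-conductance
    level and response features, and temperature and first-derivative
    features; per-subject max-min normalization into labeled feature
    tables; and a two-tier nonparametric screening procedure
    (Kruskal-Wallis, pairwise Mann-Whitney U with Benjamini-Hochberg
    correction) in binary and overall modes with significance-count
    summaries and cross-test feature comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    signal,
    splines,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
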