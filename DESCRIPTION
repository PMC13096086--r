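Package: freqstate
Title: Frequency-Resolved EEG Microstate Analysis and Consciousness-State
    Classification
Version: 0.1.0
Authors@R:
    person("freqstate", "developers", email = "freqstate@example.org",
           role = c("aut", "cre"))
Description: A pipeline for frequency-resolved EEG microstate analysis of
    anesthetic-induced transitions of consciousness. Provides band-specific
    preprocessing (zero-phase Butterworth filtering, polyphase resampling,
    common-average referencing), multitaper spectral estimation with Slepian
    tapers, global field power (GFP) peak extraction, polarity-invariant
    modified k-means microstate segmentation with GEV and cross-validation
    model-order criteria, multi-level template averaging and sorting,
    back-fitting with midpoint interpolation and temporal metrics (duration,
    occurrence, coverage, individual explained variance), repeated-measures
    group statistics with Lilliefors normality screening, and hybrid
    NCA + MRMR feature selection feeding linear SVM and random-forest
    classifiers under leave-one-out and stratified five-fold
    cross-validation. A synthetic-data generator with known microstate
    ground truth supports end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    clue,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
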