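Package: depscreen
Title: EEG-Based Depression Screening Pipeline with Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for time-domain EEG depression screening:
    simulation of multichannel EEG cohorts with group-dependent band-power
    structure and subject random effects, a Butterworth band filter bank over
    the canonical EEG bands and their combinations, non-overlapping
    segmentation, per-channel time-domain features (Hjorth activity, mobility
    and complexity, Shannon and log-energy entropy, kurtosis, skewness), a
    ten-preset KNN/SVM classifier grid, stratified cross-validation and
    70/30 hold-out protocols with confusion-matrix metrics, and factorial
    sweep experiments over segment length, feature set, frequency band and
    scalp region.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    class,
    withr
Config/testthat/edition: 3
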