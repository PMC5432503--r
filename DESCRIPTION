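Package: ctfem
Title: Backward Decoding and Forward Encoding Models for Attentional
    Selection in EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multivariate analysis of epoched EEG for tracking feature-based
    attentional selection. Implements per-timepoint linear-discriminant
    backward decoding of target position with stratified k-fold
    cross-validation, covariance-based (Haufe) activation patterns, a
    delta-basis forward encoding model yielding channel tuning functions
    (CTFs), inversion of that model to reconstruct scalp topographies for
    stimulus positions that were never presented, N2pc
    contralateral-minus-ipsilateral difference waves, the sliding-window step
    algorithm for ocular artifact detection, and cluster-based permutation
    statistics over time samples and electrode neighbourhoods. Ships a
    synthetic-data generator with a known position-tuned generative model so
    that every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
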