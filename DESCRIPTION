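Package: cofluct
Title: Co-Fluctuation-Resolved Functional Connectivity, Fingerprinting and
    Phenotype Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decomposes parcellated resting-state BOLD recordings into edge
    time series, ranks time points by their root-sum-of-squares co-fluctuation
    amplitude, and estimates functional connectivity from high-, low- or
    intermediate-amplitude subsets of the scan. Provides connectome
    fingerprinting metrics (identification accuracy and differential
    identifiability) with bootstrap inference, phenotype prediction with
    Pearson-kernel ridge regression and connectome-based predictive modelling
    under nested, family-grouped, confound-consistent cross-validation, a
    Bayesian region-of-practical-equivalence comparison of cross-validated
    models, and structure-function coupling analyses. A seeded multi-subject
    BOLD cohort simulator with known subject covariance, co-fluctuation
    events, family structure, confounded phenotypes and structural
    connectivity supports parameter-recovery testing of the full pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
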