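Package: macroeeg
Title: Macroscale Resting-State EEG Features and Random-Forest Analysis
Version: 0.1.0
Authors@R: person("Macroeeg", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extraction of macroscale spectral, functional-connectivity and
    minimum-spanning-tree network features from multichannel resting-state
    EEG recordings, with univariate group comparison (Mann-Whitney U with
    Holm-Bonferroni correction), balanced random-forest classification and
    permutation-validated random-forest regression of symptom-change
    outcomes. Includes a synthetic-data module that generates EEG-like
    multichannel recordings with controllable phase and amplitude-envelope
    coupling, an instantaneous-mixing volume-conduction surrogate, and
    synthetic cohorts with planted group effects and symptom trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
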