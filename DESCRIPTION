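Package: appraisalDecode
Title: Decoding Emotion-Antecedent Appraisal Checks from Epoched EEG and Facial EMG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting emotion-antecedent appraisal checks (novelty,
    intrinsic pleasantness, goal conduciveness, control, power) in epoched
    multi-channel EEG and facial EMG recordings. Implements the full decoding
    protocol: signal conditioning and artifact rejection, factorial-to-check
    relabeling, within-participant trial averaging, log-spaced filter-bank
    spectro-temporal feature extraction, participant-independent nested
    three-fold cross-validation with a linear maximum-margin classifier, and
    performance quantification via unweighted average recall against exact
    binomial empirical chance levels. A seedable synthetic-data generator
    produces ERP-like epoch sets with factorial condition structure, 1/f
    background noise and participant/trial variability, so every stage is
    testable without access to laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
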