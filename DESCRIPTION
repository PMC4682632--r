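Package: ngome
Title: Sequence-Based Prediction of Spontaneous Asparagine Deamidation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts non-enzymatic deamidation half-times of internal
    asparagine residues in proteins from sequence alone, combining
    dipeptide-scale intrinsic half-times for the Asn/N+1 pair with
    protection factors derived from predicted alpha-helix state and
    intrinsic disorder. Includes parsers for external secondary-structure
    and disorder predictor output, deterministic fallback predictors,
    ROC/AUC evaluation with a paired DeLong test, the repeated
    stratified-split grid training that fits the protection weights,
    whole-protein first-deamidation half-times, proteome-scale batch
    prediction with turnover correlation, and a synthetic fixture
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
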