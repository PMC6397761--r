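Package: miace
Title: Multiple Instance Adaptive Cosine Estimator for Hyperspectral Crown Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised classification of hyperspectral tree crowns from
    bag-level (crown-level) labels. Implements the multiple instance adaptive
    cosine estimator (MI-ACE), which learns a discriminative target signature
    in whitened background space by alternating instance selection and a
    closed-form signature update, and extends it to multiclass problems with a
    one-vs-one voting scheme including threshold training, bag-level
    confidence aggregation, and hierarchical genus-to-species prediction.
    Includes water-band removal and background whitening preprocessing, the
    competition evaluation metrics (rank-1 accuracy, cross entropy, per-class
    accuracy, specificity, precision, recall, F1) with epsilon-softening of
    crisp probabilities, a synthetic bag generator following the Gaussian
    background plus scaled-target model, and stratified two-fold
    cross-validation at the bag level.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
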