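Package: ConservativeRF
Title: Conservative Random-Forest (Q)SAR Models for Endocrine-Activity Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains and evaluates conservative random-forest (Q)SAR classifiers
    for screening chemicals for endocrine receptor activity from molecular
    fingerprints. Decision trees are grown with selectable imbalance-aware
    split costs (Gini impurity, balanced accuracy, Matthews correlation,
    macro F-score), continuous descriptors are discretized into twenty
    equal-width bins per tree, and all tie-breaks prefer the stronger activity
    class so that false negatives are traded for false positives. A genetic
    algorithm post-optimizes a trained forest by capping tree depths and
    disabling trees, and a density k-nearest-neighbour applicability domain on
    a PCA embedding flags substances whose predictions are unreliable. A
    seed-deterministic synthetic fingerprint generator reproduces the class
    imbalance and descriptor structure the method targets, so the whole
    pipeline is testable without external chemistry software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    ranger,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
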