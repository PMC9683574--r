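Package: shapaal
Title: Shapley-Attributed Ablation with Augmented Learning for Time Series Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-stage classifier for small labelled collections of univariate
    time series (physiological signals such as ECG among them). A residual
    network whose input and identity connections carry controlled additive
    Gaussian perturbation is trained on the full training set; every training
    sample is then valued as a player in a transferable-utility coalition game
    and samples with non-positive Shapley value are discarded by the
    null-player rule; the network is re-trained on the retained subset.
    Includes exact (subset-formula and permutation-enumeration) and
    Monte-Carlo Shapley estimators, a gradient-based per-sample attribution
    path, a reader/writer for UCR-archive-dialect files, a synthetic data
    generator with ground-truth mislabels, the evaluation metrics (test
    accuracy, mean per-class error, learning gain, training-insufficiency
    factor, differential benchmark gain, mode-over-seeds aggregation), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
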