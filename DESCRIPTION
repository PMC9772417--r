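Package: classlimit
Title: Data-Inherent Limits of Classification Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and reaching the data-inherent limit of
    classification accuracy that arises when class-conditional densities
    overlap. Provides an ideal-classifier confusion-matrix calculator (grid
    integration and Monte Carlo), a two-level superstatistical generator of
    labeled Gaussian datasets with controllable dimension, class separation
    and feature correlation (the DSC model), three reference classifiers
    (kernel-density naive Bayes, correlated multivariate-Gaussian Bayes, and
    a one-hidden-layer perceptron) plus random dimensionality expansion, the
    General Discrimination Value (GDV) cluster-separability statistic,
    interpretable Fourier and autocorrelation features for epoch-structured
    signals with a synthetic sleep-recording generator, and an embedding
    analysis pipeline (autoencoder, deep classifier, multidimensional
    scaling, layer-wise GDV).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
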