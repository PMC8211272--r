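Package: dnv1
Title: Learnable Divisive Normalization Encoding Models of Primary Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Image-computable encoding models of macaque V1 spiking responses
    built around a learnable divisive normalization stage. A convolutional
    subunit core (rectified filter bank with bias-only batch normalization)
    feeds a divisive normalization layer whose normalization pool weights,
    exponents and semi-saturation constants are fitted to data by Poisson
    regression, followed by a non-negative factorized readout and a learnable
    output nonlinearity. Includes model variants (identity/subunit,
    nonspecific normalization, spatially extended normalization pools),
    training with adaptive-moment gradient descent and early stopping,
    noise-corrected accuracy metrics (explainable variance, FEV), in-silico
    electrophysiology (cross-orientation inhibition with plaid stimuli, size
    tuning with windowed gratings), orientation-specific normalization
    analyses, and a synthetic ground-truth population simulator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    yaml,
    Matrix,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
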