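Package: tcrcfda
Title: Functional Mixed-Effects Modelling and Clustering of Time-Dependent
    Cellular Response Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of time-dependent cellular response
    curves (TCRCs) from impedance-based cytotoxicity assays. Implements
    data-driven binning of concentration levels via discrete wavelet
    features, functional k-means and Adjusted-Rand-Index similarity;
    functional linear mixed-effects models fitted by functional principal
    component analysis with BLUP score prediction, and by projection onto
    a cubic B-spline basis with REML variance components and
    Benjamini-Yekutieli-controlled group contrasts; unsupervised
    clustering of chemicals by mode of action with k-means and
    self-organizing maps; and one-way MANOVA on score vectors. A
    synthetic-data module simulates curve panels with the statistical
    structure the models assume, with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    splines,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
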