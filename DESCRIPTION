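Package: plsipa
Title: Partial Least Squares Path Modeling with a Principal-Component
    Weighting Scheme and Importance-Performance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Composite-based structural equation modeling in which each
    latent variable's outer weights are taken from the first principal
    component of its indicator block, a one-shot (non-iterative) weighting
    scheme. Provides nonparametric bootstrap inference for loadings and
    path coefficients, measurement- and structural-model evaluation
    (average variance extracted, composite reliability, cross-loadings,
    the Fornell-Larcker criterion, R-squared, goodness of fit, Q-squared
    predictive relevance), and importance-performance map analysis (IPMA)
    on a 0-100 performance scale. Includes a synthetic-data generator with
    known population structure for validation and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
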