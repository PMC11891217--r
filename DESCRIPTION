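Package: pracopt
Title: Box-Behnken and Neural-Network Surrogate Optimization of a
    Polysaccharide Extraction Process
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for optimizing a microwave-assisted polysaccharide
    extraction process from designed experiments. Implements four-factor
    three-level Box-Behnken designs with full second-order response-surface
    fits, Design-Expert-style ANOVA (partial sums of squares in coded units,
    lack of fit against pure error from center replicates, PRESS and
    predicted R-squared), and constrained maximization of the fitted yield
    surface. Provides from-scratch feedforward neural-network surrogates
    (4-h-1, tanh hidden layer) trained by batch backpropagation, by a
    real-coded genetic algorithm followed by backpropagation (GA-BP), and by
    a GA-seeded continuous ant-colony optimizer followed by backpropagation
    (GA-ACO-BP), together with R-squared/MAE/RMSE model comparison, a
    synthetic Box-Behnken experiment generator, and closed-form assay and
    first-order release-kinetics helpers for the downstream liposome
    formulation work.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
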