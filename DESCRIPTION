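Package: bgge
Title: Bayesian GGE Analysis of Multi-Environment Trials with Shrinkage Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the genotype main effects plus genotype-by-environment
    interaction (GGE, or site regression) linear-bilinear model to
    multi-environment trial data by Gibbs sampling. Two prior regimes are
    available for the singular values of the bilinear term: a flat conjugate
    prior and a maximum-entropy hierarchical prior that shrinks
    weakly-supported singular values toward zero. Includes von Mises-Fisher
    sampling of singular vectors in orthogonality-corrected subspaces,
    order-constrained singular-value updates, Raftery-Lewis and
    Heidelberger-Welch convergence diagnostics, effective sample size,
    information-criterion model selection (AIC, BIC, AICM), information-rate
    screening of bilinear axes, k-fold cross-validation with PRESS and
    predictive correlation, and posterior biplot inference: bivariate
    credible regions, HPD intervals, the average-environment axis, ideal
    genotype distances, environment cosines, mega-environment subsetting and
    who-won-where sectors. A simulator reproduces sign-structured crossover
    interaction designs for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
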