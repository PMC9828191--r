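Package: rrsel
Title: Phenotypic Selection on Composite Traits via Bayesian Reduced-Rank Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates phenotypic selection on high-dimensional composite
    traits such as floral scent blends. A Bayesian reduced-rank regression
    jointly infers a weighted composite trait axis (for example a "scent
    selection axis" over many volatile emission rates) and the selection
    gradient acting on it, using a conditionally conjugate Gibbs sampler.
    Provides mean- and variance-scaled selection gradients, posterior
    support, back-projection of axis selection onto the original compounds,
    multiple-regression baselines, cross-validated predictive r-squared,
    and a moment estimator of among-dataset variance in selection gradients
    corrected for sampling error. Includes a synthetic-data generator
    emulating correlated, right-skewed volatile emissions, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
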