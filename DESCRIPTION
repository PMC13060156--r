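Package: citemp
Title: Quantifying Temperature-Sensitive Cytoplasmic Incompatibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical machinery for quantifying temperature-sensitive
    cytoplasmic incompatibility (CI) in Wolbachia-Drosophila systems: a
    zero-inflated binomial mixed model for egg-hatch counts with an
    observation-level random effect fitted by Gauss-Hermite quadrature,
    odds-ratio and ratio-of-odds-ratio contrasts with FDR control and
    partial eta-squared effect sizes; permutation tests and Euclidean
    sequential-sum-of-squares PERMANOVA for development time; delta-Cq
    relative quantification of symbiont and phage densities with factorial
    linear models, type-II F tests and partial omega-squared; Monte-Carlo
    propagated Kendall tau concordance with probability of direction; and
    Bayesian phylogenetic mixed regression with a chronogram-derived
    covariance, Gibbs-within-slice sampling, Bayesian R-squared and
    split R-hat diagnostics. A synthetic-data module generates all pipeline
    inputs with the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
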