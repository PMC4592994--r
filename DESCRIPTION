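Package: ordpg
Title: Bayesian Ordinal Regression via Polya-Gamma Data Augmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Exact Gibbs sampling for Bayesian logistic ordinal regression
    (BLOR) of latent-liability threshold models using Polya-Gamma data
    augmentation, with the Bayesian probit ordinal model (BPOR) as the
    omega-equal-one special case. Supports fixed-effect and whole-genome
    ridge (p >> n) design matrices, an optional polygenic term with a
    genomic relationship matrix, bespoke maximum-likelihood cumulative-link
    baselines, the k-scaled probit-to-logit approximation, halved Brier
    scores, DIC, credible sets for per-category probabilities, replicated
    simulation studies, and 90/10 cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
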