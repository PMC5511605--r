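Package: optimet
Title: Optimal Multi-Environment Trial Design for Crop Model Parameter
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects the subset of candidate field environments (location by
    sowing date combinations) that best identifies the genetic parameters of
    a wheat phenology crop model, using a Bayesian design criterion driven by
    likelihood weights between a priori parameter vectors. Includes the
    three-phase phenology simulator (vernalization, photoperiod, phyllochron),
    a Metropolis-within-Gibbs sampler for per-variety parameter estimation
    from heading-date phenotypes, synthetic weather and genotype generators,
    G-BLUP genomic prediction and mixed-model association scans, and a
    simulation pipeline benchmarking design strategies (random, reasoned,
    expert, criterion-optimal) by estimation error, QTL detection power and
    heading-time prediction accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
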