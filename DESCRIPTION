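Package: fgcmhier
Title: Hierarchical Bayesian Analysis of Fecal Glucocorticoid Metabolites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-level hierarchical Bayesian regression of fecal
    glucocorticoid metabolite (fGCM) concentrations in longitudinally sampled
    wild elephants. Provides a study-design-faithful synthetic data generator
    (individuals, seasonal NDVI covariates, repeated dung samples, outlier
    contamination), preprocessing (per-individual 3-SD outlier discard,
    column standardization, two-level design assembly), an exact blocked
    Gibbs sampler for the conjugate linear-Gaussian model, Gelman-Rubin
    convergence diagnostics, posterior predictive checks (Bayesian p-values
    for the mean and SD of each model level), and a seeded pipeline with a
    parameter-recovery harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    coda,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
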