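Package: surveyfuse
Title: Data Fusion of Health Surveys with Validated Multiple Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical matching (data fusion) of a small clinical-examination
    donor survey into a large self-report recipient survey. Implements three
    stochastic single-imputation engines (k-nearest-neighbour hot deck,
    sequential regression with parameter draws, and a data-augmentation
    sampler under a joint latent-normal model), multiple imputation with
    Rubin within/between variance pooling, an eight-statistic suite for
    validating fused data against observed donor values, a bootstrap harness
    for comparing imputation methods, and a clinical pipeline that chains
    regression submodels for risk factors and estimates condition prevalences
    with donor-vs-fused precision ratios. A synthetic-population generator
    with known ground truth supports end-to-end testing without access to
    restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
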