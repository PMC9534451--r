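Package: microcensus
Title: Estimating Human Population Size from Mixed Microbiome Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric estimation of the number of human contributors to a
    mixed (e.g. sewage) gut microbiome sample. Implements a diagonal
    Hotelling-type T statistic on relative taxon abundances, per-size bootstrap
    null distributions with Gaussian kernel density estimates, maximum
    likelihood population-size estimation with one-sided confidence intervals,
    an evaluation harness (train/validation/test splits, feature-count tuning,
    simulation benchmarks), sewage preprocessing (family-level taxonomic
    filtering and Welch t-test feature screening), species abundance
    distribution model comparison by rank-by-rank R-squared, pooled-sample
    sub-species diversity metrics from SNV allele counts, and synthetic-cohort
    generators for testing every step without external data.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
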