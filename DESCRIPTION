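Package: swipr
Title: Similarity-Weighted Informative Priors for Bayesian Multiple Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the similarity between a focal study and a body of
    previously conducted studies, and uses it to weight informative prior
    distributions in Bayesian multiple regression. Similarity combines a
    propensity-score generalizability index (Bhattacharyya overlap of
    sampling-propensity-score densities), between-study heterogeneity from a
    hierarchical Bayesian random-effects meta-analysis of Fisher-z partial
    correlations, and moderator-explained heterogeneity from the matching
    mixed-effects model, into a single weight in [0, 1] that is used as the
    power on the informative prior. Includes the comparator priors
    (pooled non-informative, normalized power prior, robust meta-analytic
    predictive prior), a simulation-study generator and runner, and broom-style
    tidiers and ggplot2 plots for the result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
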