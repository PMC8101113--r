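Package: bymrisk
Title: Bayesian Disease Mapping of Areal Relative Risk with the
    Besag-York-Mollie Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small-area disease mapping of count data. Computes
    expected counts and standardized morbidity ratios from county-level
    incidence tables, builds spatial adjacency graphs from neighbor lists or
    polygon contiguity, and fits non-spatial and Besag-York-Mollie (BYM)
    Poisson regression models by Metropolis-within-Gibbs Markov chain Monte
    Carlo with an intrinsic conditional autoregressive (ICAR) spatial prior.
    Posterior summaries include per-area relative risks, 95 percent credible
    intervals and exceedance probabilities, rendered as static and
    interactive choropleth maps. Ships a transcription of published Georgia
    county prostate cancer incidence characteristics (2012-2016) as a worked
    fixture, and a synthetic areal data generator for validating inference by
    parameter recovery.
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
    grDevices,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    coda,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
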