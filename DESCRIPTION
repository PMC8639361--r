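Package: forestdid
Title: Stacked Difference-in-Differences Evaluation of Land-Titling Effects on Deforestation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating staggered community land-titling policies
    against annual forest-loss outcomes. Extracts per-polygon annual
    deforestation rates from loss-year rasters (zonal statistics with
    optional forest-class masks), builds stacked difference-in-differences
    panels over titling cohorts with designated-but-untitled control areas,
    and fits Poisson pseudo-maximum-likelihood regressions with absorbed
    high-dimensional fixed effects and cluster-robust sandwich inference.
    Ships a synthetic-data laboratory (panel and landscape generators with
    known treatment effects) and Monte-Carlo experiments for parameter
    recovery, confidence-interval coverage, size control, and comparison
    with naive pooled two-way fixed-effects fits under heterogeneous
    staggered effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
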