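Package: peatturnover
Title: Taxonomic and Functional Turnover Analysis for Peatland Plant Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the decoupling of taxonomic and functional
    turnover in peat-bog plant communities. Provides community data
    preparation (site-level averaging, rare-species filtering, rarefaction),
    taxonomic and functional diversity indices (Gini-Simpson diversity,
    community-weighted means, Gower trait dissimilarity, Rao quadratic
    entropy, functional redundancy, Bray-Curtis and Rao-decomposition
    functional beta diversity), generalized dissimilarity modelling with
    monotone I-spline transforms and permutation-based backward elimination,
    a hierarchical species-environment co-response model with correlation
    decomposition and threshold-network clustering, seven community
    re-assembly null models scored by standardized effect sizes, gradient
    regression summaries, and a synthetic-data generator that emulates the
    statistical structure of European bog vegetation surveys.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    pracma,
    geosphere,
    vegan,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    e1071,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
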