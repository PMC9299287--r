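Package: ebsbm
Title: Empirical Bayes Shrinkage Estimation and Model Selection for
    Stochastic Block Models and Graphons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hierarchical Beta-Binomial modeling of block connectivity in
    undirected networks. Provides an empirical Bayes shrinkage estimator of
    the stochastic block model connectivity matrix, a penalized marginal
    likelihood (ICL-style) criterion for selecting the number of
    communities, piecewise-constant graphon estimation with identifiability
    relabeling, regularized spectral clustering as a partition front-end,
    simulators for benchmark block-model and graphon designs, and the
    evaluation metrics (node-level and integrated mean squared error,
    selection deviation summaries) needed to benchmark the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
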