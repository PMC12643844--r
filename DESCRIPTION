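Package: milscope
Title: Assessing Meaning in Life from Short Social-Media Posts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing Meaning in Life (MIL) and its associated
    factors from short social-media posts. Implements a corpus pipeline
    (cleaning, seed-keyword screening, multi-annotator consensus with
    Cohen's kappa, similarity-gated data augmentation), a three-stage
    classifier cascade built on layer-wise encoder summary vectors with a
    multi-window convolutional head (relevance, then search-for-meaning and
    presence-of-meaning levels), a reason-anchored semantic dependency graph
    algorithm that extracts MIL-associated factor terms and maps them onto
    closed-vocabulary lexicon categories, and multi-level psychometric
    network analysis of those factors across subgroups: regularized
    partial-correlation networks selected by the extended Bayesian
    information criterion, expected-influence centrality, density,
    modularity with Louvain community detection, and permutation-based
    network invariance comparisons. A synthetic-data generator provides
    class-conditional posts, annotation tables, role triples and Gaussian
    samples with planted sparse precision structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stringi,
    MASS,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
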