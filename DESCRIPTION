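Package: upho
Title: Explainable Population-Health Surveillance with Knowledge Graphs and Support Vector Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for census-tract-level population health surveillance that
    combine semantic knowledge graphs with explainable machine learning.
    Generates synthetic tract tables with configurable marginal statistics and
    rank-correlation structure, screens social-determinants-of-health features
    (Spearman correlation, variance inflation factor), fits a linear-kernel
    epsilon-insensitive support vector regression with cross-validated grid
    search, scales feature importances to 0-100 and computes closed-form
    Shapley attributions for single neighborhoods, builds an ontology-backed
    population knowledge graph, enriches it by Datalog-style forward chaining
    and machine-learned predictor edges, and traces scored causal pathways
    from neighborhood exposures to disease outcomes with textual explanations
    and recommendations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    igraph,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse
Config/testthat/edition: 3
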