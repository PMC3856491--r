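Package: gepess
Title: Essential-Protein Prediction with Gene Expression Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts essential proteins in protein-protein interaction (PPI)
    networks by evolving a symbolic classifier with gene expression
    programming (GEP). Computes seven node centralities (degree, betweenness,
    closeness, subgraph, eigenvector, information, and the edge-clustering
    coefficient sum NC), co-expression-weighted composites (PeC, WDC) and an
    orthology propagation score (ION), assembles a max-normalized feature
    table, evolves Karva-encoded expression trees under the SSPN fitness
    (the product of sensitivity, specificity, and the two predictive values),
    and evaluates ranked predictions with stratified cross-validation,
    ROC/AUC and a full confusion-metric suite. A seeded synthetic-data
    generator produces desk-scale PPI studies with planted essentiality
    signal so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
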