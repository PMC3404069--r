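Package: eqtlcommittee
Title: Committee-Based eQTL Network Mapping with Random Forests and
    Penalized Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multivariate expression quantitative trait locus (eQTL)
    network inference by committees of machine-learning marker-importance
    scores. Implements four base scorers per target gene (random-forest
    selection frequency, unscaled random-forest permutation importance,
    LASSO and Elastic Net absolute coefficients), unfiltered committees of
    scaled and centered scores, a sparse LASSO-gated filtered committee,
    ranked directed edge-list prediction with top-K truncation and random
    padding, and ROC/precision-recall evaluation (AUROC, AUPR) against a
    gold-standard network. Includes a recombinant-inbred-line systems
    genetics simulator (linked binary genotypes, scale-free/exponential
    directed regulatory networks, steady-state expression with cis and
    trans genetic effects) so the full pipeline can be benchmarked at
    configurable scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    randomForest,
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
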