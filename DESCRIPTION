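Package: patternwalk
Title: Pattern-Constrained Random Walks and Link Prediction on
    Heterogeneous Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Embeds typed (heterogeneous) knowledge graphs by sampling
    random walks constrained by a regular pattern over node types.  The
    pattern is compiled to a deterministic finite automaton that admits or
    rejects each candidate step; admissible neighbours are chosen with an
    inverse-degree bias that suppresses hubs, first picking an edge type in
    proportion to its share of the current node's edges and then a
    neighbour within that type.  Walks that reach the pattern's terminal
    type continue in reverse through the pattern positions until the
    walk-length budget is spent.  Skip-gram embeddings trained on the walk
    corpus feed a Hadamard-feature logistic-regression link predictor with
    closed-world negative sampling, aimed at proposing pathway memberships
    for sparsely annotated (dark) kinases.  Includes curation filters for
    common association sources, a seeded synthetic knowledge-graph
    generator with planted protein-pathway structure, replicate-overlap
    robustness summaries, and walk-based interpretation of individual
    predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
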