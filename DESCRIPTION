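Package: ppicomplex
Title: Protein Complex Detection from PPI Networks via Node Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects protein complexes in protein-protein interaction (PPI)
    networks. Nodes are embedded with biased second-order random walks
    (node2vec-style alias sampling) trained by skip-gram with negative
    sampling; embedding cosine similarities weight, filter and augment the
    network; a supervised regression over eleven topological features guides
    greedy expansion of high-degree seeds into candidate complexes; a
    three-class random forest over max-pooled complex vectors keeps the
    positively labelled candidates. Includes neighborhood-affinity matching
    (precision/recall/F-score), a link-prediction benchmark (cosine, AdjustCD,
    PE-measure, mean ranking and Hits@N), and a synthetic planted-complex
    network generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    randomForest,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    nnet,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
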