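Package: relkern
Title: Graph Kernels for Biomedical Relation Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Relation extraction from biomedical text with graph kernels over
    dependency parse graphs. Implements the edge-weighted Approximate Subgraph
    Matching (ASM) kernel and the All Path Graph (APG) kernel, together with
    the surrounding machinery: CoNLL-U, unified PPI XML and PubTator corpus
    readers, entity-focus and shortest-path edge weighting of dependency
    graphs, cross-sentence graph merging for relations that span sentence
    boundaries, kernel-SVM classification over precomputed Gram matrices,
    document-level aggregation of chemical-disease candidate pairs, evaluation
    metrics (precision, recall, F1, AUC) and McNemar's paired significance
    test. A synthetic corpus generator with a plantable lexical signal makes
    the whole pipeline testable without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    kernlab,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    igraph,
    withr
Config/testthat/edition: 3
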