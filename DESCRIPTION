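Package: contextppi
Title: Cell-Type-Contextualized Protein Representations from Multi-Scale
    Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs cell-type-specific protein interaction networks from
    single-cell expression data and a reference interactome, assembles them
    with a cell-type/tissue metagraph, and learns contextualized protein
    embeddings with a multi-scale graph attention network trained by
    self-supervised link prediction and a center loss. Includes a synthetic
    data generator with planted structure, a target-prioritization
    fine-tuning head with leakage-free protein-level splits, and the
    evaluation statistics used to interrogate the embeddings (APR@K,
    similarity gaps, tissue-ontology distance retrieval, permutation tests,
    and neighborhood enrichment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    graphics,
    methods,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
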