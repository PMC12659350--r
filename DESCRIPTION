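Package: cazkit
Title: Two-Stage Annotation of Carbohydrate-Active Enzymes from Protein
    Language Model Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates carbohydrate-active enzymes (CAZymes) in protein
    catalogs using fixed-length protein language model embeddings. A
    random-forest gate first separates CAZymes from other proteins; a
    feed-forward neural network trained with inverse-class-frequency
    weighted cross-entropy then assigns a CAZy family or subfamily.
    Includes the training-set curation protocol (length filtering,
    deduplication, greedy identity clustering, negative-set homology
    purging), an HDF5 embedding store with a pluggable embedder contract,
    a benchmarking harness (precision/recall/F1, confusion matrices,
    ROC and precision-recall curves), embedding-space interpretability
    probes (exact Euclidean nearest neighbours and a sliding-window
    BLOSUM62 substitution scan), a gene-catalog differential-abundance
    workflow with Benjamini-Hochberg control and enzyme prioritization,
    and deterministic synthetic-data generators for all of the above.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    randomForest,
    rhdf5,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
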