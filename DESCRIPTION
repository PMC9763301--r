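Package: capstf
Title: Capsule Network Classification of Transcription Factors from Protein Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end deep sequence classifier that discriminates transcription
    factors (TFs) from non-TFs directly from amino-acid sequence. The model stacks
    a learned residue embedding, a bidirectional LSTM encoder, a capsule layer with
    iterative dynamic routing, and a three-layer dense head; forward and backward
    passes are implemented from scratch in compiled code. The package also provides
    FASTA/label ingestion with sequence-quality filters, fixed-length position
    windowing and tokenization, binary-classification metrics (Sn, Sp, Acc, MCC,
    AUC), capsule-feature extraction with PCA projection, position-window and
    capsule-ablation experiment harnesses, a synthetic motif-planted sequence
    generator for benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    Biostrings,
    jsonlite,
    yaml,
    optparse,
    ggplot2,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
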