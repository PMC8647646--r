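Package: hanppis
Title: Hierarchical Attention Networks for Protein-Protein Interaction Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue-level prediction of protein-protein interaction sites
    from sequence-derived features using a two-level (amino-acid and K-mer)
    hierarchical attention network over bidirectional GRU encoders. Provides
    readers for FASTA sequences, PSI-BLAST ASCII position-specific scoring
    matrices, DSSP secondary-structure output and precomputed per-residue
    embeddings; a six-block residue feature encoder (one-hot, PSSM,
    secondary structure, hydropathy, relative position, projected
    embedding); sliding-window fragment extraction with K-mer segmentation;
    a from-scratch trainable hierarchical attention model with weighted
    cross-entropy loss and Adam optimisation; evaluation, feature-ablation
    and window-sweep harnesses; attention-weight extraction for
    interpretability; and a seeded synthetic-data generator so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
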