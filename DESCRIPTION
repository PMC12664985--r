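Package: proteotag
Title: Tag-Token Classification and Interpretability for Protein Language Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens translated ORFeomes for contamination by classifying
    amino-acid sequences with a small character-level causal language model
    that emits class-tag tokens. Builds terminal-information-free chimeric
    fragment datasets and tag-suffixed full-length datasets from protein
    FASTA, trains the model with a next-token objective, and evaluates with
    per-class precision/recall/F1 plus macro and support-weighted F1. A full
    interpretability suite interrogates trained models: gradient-times-embedding
    attribution, integrated gradients from a padding baseline, reference-based
    sliding-window attribution, attribution-driven discovery of degenerate and
    strict sequence motifs, layer-wise SVD projection of hidden states, and
    motif-to-domain scanning with count-times-influence ranking. A synthetic
    proteome generator with controlled residue composition and planted motifs
    makes the whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
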