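Package: tfpipes
Title: Tissue-Specific Transcription Factor Binding Site Prediction from
    Protein Binding Microarrays and Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns k-mer binding probabilities of transcription factors
    from protein binding microarray (PBM) probe intensities using a
    biophysically motivated linear model fit by positive (non-negative)
    lasso, with iterative extension to longer and gapped k-mers.  Scores
    arbitrary DNA sequences in sliding 36bp windows, converts DNase I
    hypersensitivity tag densities into open-chromatin probabilities via a
    two-component negative-binomial mixture, and integrates occupancy with
    sequence conservation in a latent-variable graphical model to obtain
    per-site posterior probabilities of in vivo binding.  Includes
    tissue-specific activity scoring with a binomial enrichment test, a
    ChIP-seq-style bound/unbound evaluation harness (ROC AUC), and seeded
    synthetic-data generators for every input format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    stringi,
    jsonlite,
    pracma,
    withr,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
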