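Package: barcodeGBA
Title: Gene Function Prediction from Consensus Independent Transcriptional
    Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decomposes a gene expression compendium into consensus
    independent transcriptional components, builds transcriptional
    regulatory barcodes for genes and gene sets, and scores every
    gene/gene-set pair by guilt-by-association with a
    permutation-calibrated Z-score. Includes PCA whitening with an
    explained-variance cutoff, multi-restart FastICA with
    credibility-filtered consensus components, distance-correlation
    similarity with Gaussian kernel density smoothed permutation nulls,
    a PCA-based comparator (Welch-T set barcodes, Pearson similarity,
    permutation or parametric p-values), multifunctionality diagnostics,
    co-functionality networks, hierarchical clustering of barcodes and
    score profiles, and a synthetic-data generator with planted latent
    sources and gene sets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    arrow,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
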