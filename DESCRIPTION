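Package: txmodes
Title: Modality and Zipf's-Law Analysis of Gene Expression-Level Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the global shape of RNA-seq gene
    expression-level distributions. Quantifies per-locus expression as
    mapped-base coverage from SAM alignments (keeping only reads mapped in
    their entire length to a single locus tag), normalizes by locus length
    and library base total, and log2-transforms. Decomposes the resulting
    distribution into a finite mixture of univariate normals by
    expectation-maximization with BIC model selection over component count
    and variance family, classifies modality by counting mixture components
    ("peaks") and main peaks holding at least a threshold share of clustered
    genes, and tests Zipf's law by least-squares regression of log2
    expression on log2 expression rank. Includes a synthetic-data generator
    (mixture vectors, power-law vectors, SAM+FASTA fixtures with known
    coverage) for validation at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    Biostrings,
    GenomicAlignments
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    Rsamtools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
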