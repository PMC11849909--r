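Package: guidescreen
Title: Design, Specificity Profiling and Outcome Quantification for Cas9 Guide RNA Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for identifying and characterizing SpCas9
    guide RNAs against a spliced gene model with two coding isoforms.
    Enumerates and annotates NGG protospacers with spliced-CDS cut-site and
    codon indices, isoform coverage and in-frame near-cognate start-codon
    risk; performs mismatch-tolerant off-target scanning with CFD and MIT
    specificity scoring, genomic-context and paralog checks, and
    cross-species reactivity calls; quantifies indel and frameshift editing
    outcomes from amplicon reads by global alignment with a CRISPResso-style
    quantification window; and scores the downstream transcriptional
    (type-I-interferon-like) response from gene-level count matrices via
    median-of-ratios normalization, variance-stabilizing log transform,
    principal component analysis and threshold-based differential
    expression, regressed against editing rates. A seeded synthetic-data
    module generates toy genomes, gene models, amplicon reads with
    programmed indel spectra and negative-binomial count matrices so the
    full pipeline runs and is tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
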