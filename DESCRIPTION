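Package: virionseq
Title: Single-Virion Transductome Analysis from Long-Read Length Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse the DNA content of individual phage virions from
    long-read sequencing of encapsidated DNA. Delineates full-length genophores
    of normal and small-headed (phage-satellite remodelled) capsids from the
    read-length distribution by permutation-tested circular binary
    segmentation, estimates the fraction of fragmented reads of ambiguous
    origin with an exponential background model, classifies genophores by
    source element (helper phage, phage-inducible chromosomal island,
    chromosome, plasmid, or lateral-transduction hybrids), quantifies
    packaged-mobilome composition and transduction outcomes, and scores
    phage-antibiotic interactions with Bliss, ZIP, HSA and Loewe reference
    models. Ships a headful-packaging simulator that generates labelled
    synthetic long reads (terminally redundant, circularly permuted genophores
    with imprecise pac initiation, capsid switching, in-situ lateral packaging
    and length-dependent fragmentation) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
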