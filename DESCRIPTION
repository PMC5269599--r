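Package: riboTE
Title: Translation Efficiency Analysis for Paired Ribosome Profiling and
    RNA-seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies translational regulation from paired ribosome
    footprint and RNA-seq data at nucleotide resolution: masked region
    counting around start and stop codons, CPM/RPKM normalisation and
    expression filtering, translation efficiency (TE), bootstrap
    permutation differential tests with regulatory pattern classification,
    metagene profiles anchored at start and stop codons, sequence-feature
    regression of TE change (uAUG and Kozak-context scanning plus a
    built-in base-pair maximisation folding score), and gene-set overlap
    enrichment with bias diagnostics. Ships a synthetic-data generator
    with planted transcriptional and translational effects so every stage
    can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
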