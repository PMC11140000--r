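Package: sialoshift
Title: Temporal Transcriptome Profiling of Blood Feeding in Soft Ticks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable reimplementation of a whole-body
    transcriptome analysis for immature soft ticks sampled across feeding
    timepoints. Extracts coding sequences from assembled transcripts by
    homology coverage and a signal-peptide heuristic, consolidates
    redundant sequences by greedy identity clustering, removes vertebrate
    and bacterial contaminants, quantifies expression as transcripts per
    million with a replicate-consistent filter, assigns functional classes
    by scanning an ordered keyword vocabulary against homology-hit
    descriptions, tests differential expression between feeding groups
    with an exact conditional negative-binomial test, and summarises
    class-level temporal profiles, Z-score heatmaps, and multidimensional
    scaling of libraries. Ships a synthetic-data generator with planted
    ground truth so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
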