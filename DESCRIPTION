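Package: ribosnitch
Title: Detection of RNA-Structure-Disrupting Variants and
    Structure-Selected Transcript Elements
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores single-nucleotide variants by their predicted
    disruption of local RNA secondary structure. Base-pair probability
    profiles of reference and mutated mature transcripts are compared with
    windowed mean-absolute (MeanDiff) and Euclidean (EucDiff) distances,
    and variants falling in the top tails of both statistics are called
    riboSNitches. Observed riboSNitch counts per transcript element
    (5'UTR, 3'UTR, lncRNA) are tested against a neutral expectation
    simulated from an intronic 96-category trinucleotide mutation profile,
    with one-sided Fisher's exact tests and Benjamini-Hochberg control.
    Includes a pair-weight partition-function folding backend (exactly
    verifiable by structure enumeration), an adapter for RNAplfold
    unpaired-probability output, benchmark ROC evaluation, and a fully
    synthetic fixture generator for genomes, annotations and mutation
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    pROC,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
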