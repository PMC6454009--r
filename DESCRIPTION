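Package: regmutscan
Title: Transcription Factor Binding Effects of Non-Coding Somatic
    Mutations in Cancer Patient Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects recurrently mutated regulatory regions (mutation
    hotspots) in the promoters of differentially expressed genes across a
    cancer patient cohort, scores each patient's mutation block for
    changes in transcription factor (TF) binding affinity with a
    biophysical occupancy model evaluated over a ladder of chemical
    potentials, and reports TFs whose binding change is significant
    against randomized background mutation blocks drawn under uniform,
    signature-based, or tumor-derived mutation models.  Ships a seeded
    synthetic-data generator with implanted ground-truth binding effects
    so the whole pipeline can be validated end to end without external
    downloads.
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
    stats,
    utils,
    tools,
    parallel,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR,
    pheatmap,
    withr
Config/testthat/edition: 3
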