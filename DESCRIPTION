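Package: bhlhscan
Title: Genome-Wide Identification and Phylogenetic Classification of
    bHLH Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies basic helix-loop-helix (bHLH) transcription-factor
    genes in a genome or proteome by six-frame translated local alignment
    against a reference panel of annotated bHLH motifs, filters candidates
    by conservation at 19 diagnostic motif sites, and assigns each retained
    candidate to an orthologous family and higher-order group (A-F) by
    in-group phylogenetic analysis with neighbor-joining, maximum-parsimony
    and maximum-likelihood trees and bootstrap support.  Also maps introns
    interrupting the motif coding region to motif subregions (basic, helix 1,
    loop, helix 2) and summarizes their lengths, and provides a synthetic
    genome simulator with implanted motifs and ground truth for validating
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    phangorn,
    Matrix,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
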