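Package: gliscan
Title: Homotypic Ci/Gli Binding-Site Cluster Detection and Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate Hedgehog-responsive enhancers from homotypic
    clustering of Ci/Gli transcription-factor binding sites. Scores genomic
    9-mers against a position weight matrix with a MatInspector-style matrix
    similarity score, enumerates the thresholded site vocabulary, scans
    genome FASTA for strand-aware sites, builds GC-landscape-preserving
    randomized background genomes with exact site-composition correction,
    computes a clustering coefficient (observed over expected site density)
    for candidate clusters, applies a multi-stage filter cascade (cluster
    span, anchor site score, exon/repeat exclusion, site-length fraction),
    annotates clusters against gene models and CTCF boundaries, and filters
    by cross-species positional overlap. Includes a synthetic-genome fixture
    generator with a controllable GC landscape and planted sites so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
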