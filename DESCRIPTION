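Package: pirnascan
Title: piRNA Cluster Calling, Transposon Attribution and Ping-Pong
    Signatures for Ovarian Small-RNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for characterising the PIWI-interacting
    RNA (piRNA) population of an insect small-RNA library. Builds the three
    standard library strata (all mappers, genome-unique mappers, collapsed
    genome-unique), calls piRNA clusters as runs of read-dense 5-kb genomic
    windows with a bounded-gap rule and a library-size-scaled minimum,
    classifies cluster strand bias and chromatin domain, attributes piRNAs
    to transposable elements by both consensus-mismatch and repeat-mask
    overlap methods, computes ping-pong amplification signatures (1U/10A
    biases and the 10-nt 5'-overlap histogram), and profiles genic piRNAs
    per transcript (RPM, sense and 3'-UTR fractions, TE contamination).
    Ships a deterministic synthetic-genome simulator with planted clusters,
    diverged transposon copies, ping-pong pairs and genic reads, so the
    whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
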