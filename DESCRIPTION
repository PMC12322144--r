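Package: steelseq
Title: Mapping Single-Stranded DNA Breaks from Error-Prone Polymerase
    End-Labelling Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects single-stranded DNA break (SSB) sites in aligned
    sequencing reads by locating runs of mutated target bases (e.g. all
    adenines substituted or deleted) left behind by an error-prone
    nick-translating DNA polymerase operated with one dNTP omitted.
    Provides the break detector with technology-specific filtering and
    BED output, a matching read simulator that emits pre-aligned records
    with exact CIGAR/MD edit scripts and ground-truth nick positions,
    nicking-endonuclease motif site scanning and window-overlap
    coincidence analysis, and SSB frequency and genomic-region summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    optparse,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
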