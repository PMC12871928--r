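Package: frameshiftTR
Title: Tandem Repeats in Reference and Frameshifted Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares tandem repeats (TRs) between reference proteins and the
    proteins read from the same coding sequences in the +1 and -1 reading
    frames. Provides frame translation with stop-codon fragmentation, a
    self-contained tandem-repeat detector (homorepeats, short-period arrays,
    k-mer-seeded long repeats) validated against an exhaustive smallest-period
    oracle, repeat-length group classification, amino-acid composition
    profiles, consensus-motif clustering, codon rotation and codon-usage
    analysis of homorepeats, interval-annotation coverage statistics, and a
    synthetic coding-sequence generator with planted, ground-truthed repeats
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
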