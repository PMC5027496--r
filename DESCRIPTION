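Package: coverpress
Title: Lossy Coverage-Domain Compression of Spliced RNA-Seq Alignments
Version: 0.1.0
Authors@R: person("Core", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Compresses coordinate-sorted SAM/BAM files of spliced RNA-seq
    alignments into an indexed archive of run-length-encoded coverage
    vectors plus read-length and fragment-distance tallies, discarding
    read names, sequences and qualities. Alignments are recovered with
    greedy read-recovery and read-pairing algorithms, archives support
    targeted bundle, coverage and alignment queries without full
    decompression, and fidelity of the lossy round trip is quantified
    with alignment-level precision/recall, exon- and transcript-level
    similarity scores and fragment-distance distribution comparisons.
    Includes a synthetic spliced-read generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicAlignments,
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
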