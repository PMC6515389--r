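Package: mdachimera
Title: Detection and Classification of Chimeric Reads from Multiple
    Displacement Amplification Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies chimeric read artifacts produced by
    phi29-polymerase multiple displacement amplification (MDA) from
    paired-end alignments in SAM format. Soft-clipped reads are split at
    the clip boundary under a chromosome-length-dependent minimum
    subsection length, reconstructed as pseudo paired-end reads,
    realigned, and screened with a two-sided cyclical junction-overlap
    search against the reference to call direct, inverted, and insertion
    chimeras. Includes a ground-truth simulator that plants chimeric
    junctions with engineered microhomology so the whole pipeline is
    testable at desk scale, plus summary statistics and read-id filter
    lists for downstream structural-variant workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
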