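Package: tiledmcc
Title: High-Resolution Contact Matrices from MNase-Based Tiled Capture 3C Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Micro-Capture-C (MCC) libraries enriched with
    tiled capture oligonucleotide panels. Reconstructs base-pair-resolved
    proximity-ligation junctions from chimeric paired-end reads, removes PCR
    duplicates using sonication-end fingerprints with coordinate wobble, and
    builds ICE-balanced contact matrices at 20-500 bp resolution, including
    downsampled differential matrices and junction density-plot exports.
    Also includes a capture-oligo tiling designer with repeat filtering and
    a synthetic proximity-ligation read simulator with ground-truth junction
    tables, so the complete pipeline can be exercised and validated at desk
    scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringi,
    data.table,
    jsonlite,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
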