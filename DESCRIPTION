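Package: pirnaforge
Title: Simulation and Analysis of Piwi-Interacting RNA Biogenesis from Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the biogenesis of Caenorhabditis elegans
    piRNAs (21U-RNAs) from small RNA sequencing libraries. Implements
    position-weight-matrix scoring of the upstream Ruby motif and two-class
    locus classification, exact-match read assignment that separates mature
    21U-RNAs from capped precursor candidates via 5-prime-extension and
    length profiles, genotype-wise depletion statistics, antisense 22G-RNA
    quantification, differential-expression gene sets with enrichment and
    permutation tests, and a seed-controlled synthetic-data generator that
    emulates wild-type, prg-1 and prde-1 libraries with a ground-truth set
    for recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
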