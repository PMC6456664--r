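Package: dcstag
Title: Decision-Tree SNP Tagging and Barcoding of Aligned DNA Barcode Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects a minimal set of discriminating SNP positions from a
    multiple-sequence alignment of DNA barcode sequences (one record per
    species, e.g. COI) by recursively partitioning the species set with a
    balanced-split scoring rule, derives a short unique nucleotide tag per
    species by projecting its sequence onto the selected positions, and
    renders each tag as a Code 128 (set B) one-dimensional barcode in SVG or
    PNG. Includes alignment trimming, SNP column identification, mapping of
    selected positions to reference-sequence coordinates, two alternative
    (imbalanced) split strategies for comparison, and seed-deterministic
    synthetic alignment generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
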