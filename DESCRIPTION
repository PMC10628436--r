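Package: dsrnafinder
Title: Editing-Agnostic Detection of Double-Stranded RNA Regions from Long-Read RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts genomic regions that fold into long double-stranded RNA
    (dsRNA) from spliced long-read RNA-seq alignments, without relying on
    A-to-I editing evidence. Reverse transcriptases occasionally skip a
    hairpin in the template, leaving an intron-like internal deletion in the
    cDNA; the package extracts per-window features of such region-skipping
    (skipping ratio, skip length, boundary dispersion, boundary
    dinucleotides), trains a random-forest classifier against
    editing-enriched-region derived positives, scans the genome in sliding
    windows, and curates predictions by RNA secondary-structure metrics
    (minimum free energy, duplex stem length). A seeded synthetic-data
    generator produces genomes, alignments and editing catalogs with planted
    ground truth so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    pROC,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
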