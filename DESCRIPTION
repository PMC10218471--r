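Package: panelforge
Title: Design and Validation of Targeted-Capture SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design and validate liquid (in-solution targeted-capture)
    SNP genotyping panels from whole-genome resequencing data. Candidate loci
    are sourced from cross-population selective-sweep scans (Hudson Fst,
    nucleotide diversity and an XP-CLR-style composite likelihood score),
    overlap with trait-tagged QTL intervals, and mixed-model genome-wide
    association on de-regressed breeding values; a uniform-density panel of a
    requested size is then assembled by greedy gap filling. Validation metrics
    for targeted-capture genotyping are included: detection rates by depth
    threshold, flank-depth decay profiles, captured minor-allele-frequency
    spectra, and genotype concordance classification against whole-genome
    sequencing calls. A synthetic-data module generates every input with known
    ground truth (Balding-Nichols population structure, simulated sweeps,
    polygenic breeding values, capture depth with allele drop-out).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    IRanges,
    S4Vectors,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
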