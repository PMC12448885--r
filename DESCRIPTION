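Package: satscreen
Title: Scoring and Analysis of Site-Saturation Yeast Two-Hybrid Interaction Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of deep mutational scanning interaction
    screens in which a site-saturation mutagenesis library of a protein
    domain is selected for binding to partner proteins by yeast two-hybrid
    growth selection and read out by amplicon sequencing. Covers library
    design (overlapping amplicon fragments, synonymously marked wild-type
    and premature-stop spike-ins), simulation of screens with known ground
    truth, codon-level variant calling from reads, log-ratio depletion
    scoring with replicate combination and cross-fragment normalization,
    dropout curation, and downstream analyses: substitution heatmap
    matrices, per-residue aggregation for structure mapping,
    separation-of-function classification, and concordance with external
    variant annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    methods,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
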