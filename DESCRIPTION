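Package: top3lfq
Title: Label-Free Top3 Proteomics Quantification and Differential-Abundance Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-driven pipeline for label-free quantitative proteomics:
    generates synthetic data-independent-acquisition peptide tables with a
    ground-truth ledger, normalizes runs, rolls peptides up to Top3 (Hi-3)
    protein abundances, applies a multi-stage differential-abundance filter
    cascade (reversed-decoy removal, replication, peptide-count, unique-peptide,
    coefficient-of-variation and one-way ANOVA filters, volcano fold-change
    classification), calls condition-exclusive proteins, row-standardizes
    abundance profiles and clusters them by complete linkage on Pearson
    distance, and performs hypergeometric over-representation analysis with
    Benjamini-Hochberg false-discovery-rate control on local GMT gene sets.
    Includes mass-accuracy (ppm) and dynamic-range quality control and
    parameter-recovery reporting against the simulation ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
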