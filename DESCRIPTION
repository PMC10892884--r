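Package: issrpop
Title: Population Genetics of Dominant ISSR Markers and Fungal Virulence Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for binary dominant-marker (ISSR/RAPD) data from
    clonal fungal isolates and for insect virulence bioassays. Computes
    within-population diversity statistics (observed and effective allele
    numbers, Nei's gene diversity, Shannon information index, percentage of
    polymorphic loci), partitions gene diversity into within- and
    among-population components (HT, HS, GST) with gene-flow estimates (Nm),
    builds Nei genetic identity/distance matrices and UPGMA dendrograms with
    Newick export, and analyses daily larval mortality records by
    empirical-probit regression (LT50) and Kaplan-Meier survival estimation.
    Includes F-model marker simulators and log-normal time-to-death bioassay
    simulators so every stage is testable on data with known parameters.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    ape,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
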