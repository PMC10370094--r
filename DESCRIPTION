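Package: prmquant
Title: Quantification of Secretory-Protein Mistargeting by Proximity
    Labeling and Parallel Reaction Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Targeted-proteomics toolkit for quantifying cytosolic
    mistargeting of secretory proteins from proximity-labeling
    (APEX2/biotin-phenol) enrichments analyzed by parallel reaction
    monitoring (PRM). Implements in silico tryptic digestion and
    target-peptide filtering, b/y transition enumeration, extracted-ion
    chromatogram integration with co-elution/constant-ratio transition
    validation, multi-factor normalization (total ion current, endogenous
    biotin carboxylase, cytosolic compartment marker, peroxidase
    auto-labeling) with a labeling-activity diagnostic, replicate CV
    quality control, and Welch/Bonferroni fold-change statistics. A
    seeded synthetic-data generator embodies the eluate-composition model
    so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    Biostrings
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
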