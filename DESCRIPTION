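Package: gnotostat
Title: Statistics for Gnotobiotic Fly-Yeast Colonization, Growth, and
    Feeding-Preference Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of gnotobiotic Drosophila-yeast assays:
    colony-forming-unit (CFU) quantification from serial-dilution plate
    counts with quality-control rules, a time-zero-normalized relative
    persistence ratio with multi-level confidence intervals and
    persists/removed/no-change classification, absolute clearance ratios,
    optical-density growth-curve summaries with within-strain hydrogen
    peroxide inhibition calls, and a dye-based two-choice feeding
    preference index with dye-swap reconciliation. Includes seeded
    synthetic-data generators for all three assay types so every pipeline
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
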