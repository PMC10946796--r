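Package: lipidims
Title: Spatial Lipidomics Analysis for MALDI Imaging Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for MALDI imaging mass
    spectrometry (MALDI-IMS) spatial lipidomics of skeletal tissue sections:
    pixel-resolved peak-list reduction, shared target-list binning, lock-mass
    correction against a spiked deuterated internal standard, region-of-interest
    feature extraction with TIC normalization and matrix-ion background
    filtering, PCA and OPLS-DA with Pareto scaling and S-plot differential-ion
    selection, zone-wise Welch t-tests with Benjamini-Hochberg FDR control and
    fold-change gating, cross-zone overlap summaries, and adduct- and
    isotope-aware lipid annotation against an LC-MS/MS-derived reference
    library with tiered confidence scoring. Includes a seeded synthetic phantom
    generator that emulates the tissue and growth-plate-zone structure of a
    mouse knee joint, so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
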