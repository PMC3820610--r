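Package: shotgunlipids
Title: Identification and Quantification of Lipid Species from High-Resolution Shotgun Lipidomics Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Processing framework for direct-infusion (shotgun) lipidomics
    acquired as multiplexed high-resolution FT MS profile spectra. Generates a
    sum-composition lipid database from building-block arithmetic, computes
    adduct ion m/z with electron-mass correction, compiles per-scan-range
    target lists with accessory lipid features and isotope information,
    identifies species in averaged profile-mode peak lists by targeted m/z
    matching with automatic lock-mass recalibration (three-point quadratic
    centroid interpolation), merges multi-range results into a long
    database-table output, and computes internal-standard-based molar amounts
    and mol% views with quality control. Includes a deterministic synthetic
    acquisition generator for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    mzR
Config/testthat/edition: 3
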