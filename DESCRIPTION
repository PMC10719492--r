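Package: vhvlpack
Title: Prediction of the Antibody VH/VL Packing Angle from Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing and predicting the packing angle between the
    VH and VL domains of an antibody Fv region. The packing angle is measured
    as the signed torsion between best-fit vectors through eight structurally
    conserved C-alpha positions in each domain of a Chothia-numbered
    structure. Prediction uses a physicochemical encoding (side-chain atom
    count, compactness, charge, hydrophobicity) of up to 37 interface residue
    positions plus CDR loop lengths, fed to gradient-boosted regression,
    optionally gated by a three-class outlier classifier. Includes dataset
    preparation (quality filtering, residue-and-angle non-redundantization,
    train/test splitting), repeated K-fold cross-validation, the standard
    regression and classification metrics, and synthetic-structure and
    planted-signal data generators that make the whole pipeline testable
    without any structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
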