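Package: dectquant
Title: Dual-Energy CT Quantification of Gold Nanoparticle Contrast
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for quantifying gold
    nanoparticle concentrations from dual-energy computed tomography (DECT).
    Generates digital calibration phantoms and mouse-like volumes with known
    water/gold concentration maps, calibrates per-energy sensitivity
    coefficients from vial regions of interest, inverts the per-voxel
    two-material linear system to concentration maps, compares organ-level
    recovered concentrations against reference (ICP-MS-style) values, and
    computes the normalized haemolysis fraction from spectrophotometric
    absorbances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
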