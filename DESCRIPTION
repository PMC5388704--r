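Package: flowke
Title: Ventricular Kinetic Energy Analysis for 4D Phase-Contrast MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies blood kinetic energy from time-resolved
    three-directional phase-contrast MRI velocity fields. Provides a data
    model and NIfTI/JSON reader-writer for 4D flow studies, eddy-current
    compensation by first-order polynomial fits to static tissue, venc-based
    temporal phase unwrapping, periodic phase reconstruction, voxel-wise and
    region-summed kinetic-energy curves with systolic/diastolic peak
    analysis and pattern classification, ventricular volumes and global
    hemodynamics including aortopulmonary collateral flow, nonparametric
    cohort statistics, and synthetic flow phantoms with known ground truth
    for end-to-end validation. Motivated by single-ventricle (Fontan)
    hemodynamics, where diastolic kinetic energy differs between
    ventricular morphologies and from biventricular controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
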