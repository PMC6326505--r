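Package: paintbox
Title: Robust Voxel-Wise Dose Painting by Numbers Planning on PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and evaluating dose-painting-by-numbers (DPBN)
    radiotherapy treatments driven by PET standardized-uptake-value (SUV) maps.
    Provides a voxel-grid image model with world-space resampling between PET,
    CT and dose-calculation grids; digital activity/density phantoms with
    emulation of two PET reconstruction protocols (an EARL-harmonized and a
    high-resolution point-spread-function protocol); linear SUV-to-dose
    prescription maps (by numbers, by contour, and robust stacked
    combinations); ray-traced Boolean aperture generation with a pencil-beam
    dose-influence engine; a sparse interior-point linear-programming optimizer
    for aperture weights with per-voxel dose floors, ceilings and
    organ-at-risk caps; and plan-quality evaluation (quality-index maps and
    histograms, quality factor, DVH, conformity index) including adaptive
    replanning with fraction-weighted dose accumulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Matrix, RNifti, yaml, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
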