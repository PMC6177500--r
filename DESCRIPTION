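Package: wallmap
Title: Wall Shear Stress, Wall Thickness and Diameter Mapping on Arterial
    Bifurcation Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-dimensional analysis of the arterial vessel wall on
    triangulated carotid-bifurcation surfaces.  Computes per-vertex wall
    thickness, lumen diameter and wall shear stress maps from lumen and
    outer-wall surface meshes together with a co-registered three-component
    phase-contrast velocity volume; builds a cohort atlas (shared geometry)
    and averages maps across subjects; performs bootstrap inference on
    Spearman correlations between cohort-averaged maps; and fits
    interaction-term linear regressions of wall thickness on wall shear
    stress and diameter to predict individual three-dimensional wall
    thickness maps.  Includes a synthetic bifurcation cohort generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    graphics,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
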