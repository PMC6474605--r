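Package: rbcshape
Title: Coarse-Grained Red Blood Cell Membrane Shape Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Energy minimisation of a coarse-grained triangulated red blood
    cell membrane under the bilayer coupling model. Provides icosphere mesh
    construction and refinement, discrete bending and curvature measures on
    triangle meshes, worm-like-chain spectrin network elasticity with
    shear-modulus calibration, constraint energies for membrane area, cell
    volume, bilayer-leaflet area difference and total membrane curvature,
    damped relaxation to minimum-energy configurations reproducing the
    stomatocyte-discocyte-echinocyte shape sequence, and triangulated-mesh
    morphometry (principal-axis extents, shape factor, per-vertex curvature)
    for comparing predicted and observed cell shapes. Meshes interchange in
    OFF, ASCII PLY and legacy ASCII VTK polydata formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
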