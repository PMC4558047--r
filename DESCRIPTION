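Package: obci
Title: Optode-Bead Chemical Imaging of Surface pH Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Reconstructs continuous, time-resolved pH maps of a surface from
    reflectance images of sparse colorimetric reporter microbeads immobilized
    above the surface. Provides Pythagorean (unit-norm) RGB normalization,
    monotone color-to-pH calibration, chroma-based bead segmentation, Delaunay
    (piecewise-linear) interpolation of scattered bead colors, radial ring
    averaging around a pore source, temporal interpolation, and tracking of an
    iso-pH front radius over time. Includes a radial diffusion-titration
    simulator (2D lateral and 3D hemispherical geometries, with the water ion
    product enforced everywhere) and a synthetic bead-image renderer, so the
    full pipeline can be exercised end to end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    interp,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    deldir,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
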