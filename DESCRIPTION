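Package: icrsim
Title: Corneal Optomechanics of Intracorneal Ring Segment Implantation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale analysis pipeline for the optomechanics of
    intracorneal ring segment (ICRS) implantation in healthy and
    keratoconic corneas. Generates synthetic corneal elevation surfaces
    (biconic base shapes, asymmetric keratoconic cones, parametric
    ICRS-induced deformation), solves a simplified Yeoh hyperelastic
    membrane inflation problem with inverse stress-free geometry
    recovery, fits biconic surfaces and computes clinical sagittal
    (axial) curvature maps, decomposes anterior elevation into
    sixth-order Zernike aberrations with OSA indexing, and evaluates
    the refraction arithmetic (radius-to-power conversion, mean
    meridional power, axial-length myopic shift, effective refractive
    change) used to compare symmetric and progressive asymmetric ICRS
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
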