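Package: nucmorph
Title: 3D Nuclear Morphometry and Actin-Cap Cell Mechanics on Synthetic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies three-dimensional nuclear morphology from confocal-style
    z-stacks (volume, thickness, projected area and shape factor, altitude-resolved
    lateral bumpiness from smoothed amplitude profiles, and apical surface
    roughness), measures cell orientation as the longest-chord angle of a binary
    mask, and solves a linear-elastic finite-element model of an adherent cell
    under uniaxial stretch with and without perinuclear actin-cap fibers,
    reporting focal-adhesion reaction forces and nuclear von Mises stress.
    Ships a synthetic-phantom generator (lobed ellipsoidal nuclei, calibration
    microspheres, oriented cell masks) so the whole pipeline is testable against
    analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    signal,
    tiff,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
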