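Package: anisokin
Title: Kinematic Analysis of Anisotropic Growth in the Monocot Leaf Growth Zone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Three-dimensional kinematic analysis of the grass leaf growth
    zone. Smooths cell- and organ-level size profiles onto a regular
    spatial grid, delimits the growth zone by the 95%-of-mature-size
    criterion, and derives cell production rate, cell division rate, cell
    cycle duration, meristem and elongation-zone cell numbers and
    residence times, cell flux, velocity and relative elemental growth
    rate profiles, zone-averaged relative growth rates in length, width
    and thickness, and growth anisotropy ratios, with descriptive
    genotype comparisons. Includes a steady-state growth-zone simulator
    with known ground truth for validation, and an intensity-cutoff
    line-probe procedure to quantify blade thickness from grayscale
    cross-section images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
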