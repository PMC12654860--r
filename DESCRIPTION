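Package: micropress
Title: Single-Cell Mechanics from Parallel-Plate Compression
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-cell stiffness measurement by
    two-plate (parallel-plate) compression with a gravimetrically
    calibrated nanonewton force sensor. Provides force-sensor calibration
    from rotation sweeps, image-based measurement of cell geometry
    (contact length and cell width), stress-strain curve construction,
    elastic-modulus extraction by high-strain linear regression,
    power-law viscoelastic (rheology) fitting across indentation speeds,
    and population-level stiffness statistics including bimodality
    detection. A built-in virtual instrument simulates calibration
    sweeps, viscoelastic cell compression, bright-field-like micrographs,
    and condition-labelled cell populations, so the full pipeline is
    testable end to end without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
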