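Package: spimcal
Title: Design Calculus and Characterization Pipelines for Large
    Field-of-View Light-Sheet Microscopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and characterizing selective plane
    illumination (light-sheet) microscopes built around large-etendue
    detection optics and large-format sensors. Provides the closed-form
    design calculus linking lens, sensor, and tissue-expansion parameters
    to resolution, coverage, and voxel throughput (etendue, Nyquist
    sampling, tile planning, light-collection scaling), plus four
    image-based characterization pipelines: bead-based point spread
    function field mapping, field-curvature estimation from through-focus
    Ronchi-ruling stacks, radial lens-distortion profiling from dot-grid
    targets, and camera signal-to-noise comparison. Seeded synthetic scene
    generators with paired ground truth make every pipeline testable
    without access to an instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
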