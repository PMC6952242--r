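Package: caliper3d
Title: Scale-Invariant 3D Linear Measurements for Volumetric Medical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless implementation of a virtual-reality style linear
    measurement system for volumetric medical images, built around a
    parent-child transform scene graph. Measurements are anchored to the
    image so they track its pose, and measured distances are inversely
    scaled by the zoom of a designated reference-scale node so that they
    stay in true anatomical millimetres under any rigid motion or uniform
    zoom. Includes NIfTI and MetaImage volume I/O with voxel/physical/world
    coordinate mapping, a synthetic ultrasound calibration-phantom generator
    (cylindrical low-scatter inserts in speckle) with an automated
    full-width-at-half-contrast caliper, a simulator of observer measurement
    sessions with per-tool endpoint noise and display quantization, and the
    evaluation statistics of inter-tool agreement studies: accuracy and
    precision summaries, agreement against a reference tool, paired t-tests
    and intra-user variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
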