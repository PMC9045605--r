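Package: histostack
Title: Blockface-Anchored 3D Reconstruction of Serial-Section Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs 3D multi-contrast volumes from serially sectioned,
    differently stained 2D microscopy images by registering every section to
    an undistorted blockface reference stack. Implements a forward-backward,
    multi-target deformable registration scheme driven by mutual information,
    with boundary and vessel feature maps as auxiliary channels, interslice
    linear intensity harmonization, guided nonlocal-means interpolation of
    per-stain sampling gaps, staged 3D alignment of MRI to blockface space,
    interslice-distance quality control, and microstructure mapping
    (structure-tensor orientation, vessel density). A synthetic phantom
    generator with full ground truth makes every stage testable by recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
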