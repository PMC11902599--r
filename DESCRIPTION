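Package: fluorosfm
Title: Combined Structural and Functional 3D Plant Imaging by Turntable
    Structure from Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a 3D plant surface from two monocular views taken
    at a small turntable angle step and overlays UV-induced blue-green
    fluorescence disease signals onto the recovered structure.  Spectral
    frames taken through red, green and blue filters are combined into an
    excess-green (ExG) channel, digitally upsampled with bicubic
    interpolation, matched across views with SIFT keypoints and a
    FLANN-style approximate nearest-neighbour ratio test, and reprojected
    to world coordinates through a 4x4 perspective (Q) matrix built from
    the camera intrinsics.  A green-filter frame captured under 365 nm UV
    excitation is thresholded into a disease mask, registered onto the
    point cloud, and summarised as a surface-coverage statistic.  Includes
    a seeded synthetic-scene generator (textured plant-like surface with
    ground-truth depth, correspondences and an injected fluorescence
    patch) so that every stage is testable without camera data, plus
    experiment runners for channel-contrast and angle-step studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
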