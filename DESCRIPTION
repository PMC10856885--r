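Package: stereonut
Title: Stereo Vision Tracking of Climbing-Plant Nutation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the 3D trajectory of a climbing plant's shoot tip
    from synchronized top- and side-view time-lapse image sequences. Provides
    pinhole camera modelling with radial and tangential lens distortion,
    chessboard-based single-camera and stereo-rig calibration with
    reprojection-error reporting, per-pixel Gaussian-mixture background
    segmentation with lighting-change detection and model resets,
    epipolar-guided tip detection using geodesic (minimum-path) analysis of
    the segmented plant contour, temporal tip selection with gap
    interpolation and manual-correction merging, photoperiod-based stereo
    synchronization, two-view triangulation with per-frame reprojection-error
    auditing and CSV export, and a ground-truthed synthetic scene generator
    that renders stereo sequences of a nutating tip inside a cylindrical
    growth booth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, png, yaml, minpack.lm, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
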