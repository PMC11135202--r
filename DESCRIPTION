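Package: aortrack
Title: Centerline Tracking and Maximal Diameter Measurement of Segmented Aortas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Automated measurement of segmented 3D aortas. Given a binary
    voxel mask (NIfTI) or a watertight surface (STL) of an aortic arch, the
    package tracks the vessel centerline from the diaphragm towards the
    aortic root by stepwise extrapolation and a "wobble" search for the
    plane of minimal connected cross-sectional area, and reports the maximal
    (Feret) diameter of that cross-section at every step. Includes analytic
    tube phantoms with exact ground truth, intraclass-correlation agreement
    statistics against reference measurements, per-step review renderings,
    and a small command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
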