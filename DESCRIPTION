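Package: histomri
Title: Spatial Registration of 3D Tumor Histology to In Vivo MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a 3D histology volume from serially sectioned,
    H&E-stained tumor slices and registers it to in vivo MRI through an
    intermediate ex vivo MRI, using a reference cutting plane for
    initialization and a three-stage (rigid, affine, B-spline) intensity-based
    registration with mutual information. Provides transform composition and
    Jacobian-based volume-change estimates, landmark-based accuracy
    evaluation, intensity-PDF interquartile tissue segmentation, and a seeded
    synthetic tumor phantom generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
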