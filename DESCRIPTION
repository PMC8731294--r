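Package: spinereg
Title: Deformable Registration and Segmentation Toolkit for Spine MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intensity-based nonrigid registration and semantic
    segmentation of lumbar spine magnetic resonance images. Implements a
    cubic B-spline free-form deformation transform, mutual-information
    similarity from joint intensity histograms, a bending-energy
    regularizer on the displacement field, a greedy multiresolution
    optimizer, a compact U-net segmenter trained with a soft-Dice
    objective, and standard evaluation metrics (Dice, Jaccard, mean
    target registration error). A synthetic spine phantom generator with
    known ground-truth deformations makes every component testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
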