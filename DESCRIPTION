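Package: osteovasc
Title: Quantitative 3D Morphometry of Bone, Vasculature and Osteolytic
    Metastases in Contrast-Enhanced Micro-CT Label Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative three-dimensional analysis of
    contrast-enhanced micro-computed tomography images of metastatic bone:
    compartment volume fractions (BV/TV, VV/TV, Me.V/TV), local vessel
    thickness by maximal inscribed spheres (V.Th), vascular-metastasis
    interdistance (VMI), distance-restricted volume-of-interest metrics,
    multi-class Dice evaluation of segmentations, and the associated group
    comparison statistics (Lilliefors normality, Bartlett variance
    homogeneity, one-way ANOVA). Includes a synthetic tibia phantom
    generator with known ground truth so every stage of the pipeline can be
    validated without scan data, a classical intensity-based baseline
    segmenter, and volume I/O for TIFF stacks, MetaImage, NIfTI and raw
    formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse
Config/testthat/edition: 3
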