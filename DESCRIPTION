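Package: shapecloud
Title: Human-Like 3D Shape Processing in Point-Cloud Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how point-cloud object-recognition networks
    represent 3D shape, and how their behaviour compares with human vision.
    Provides a procedural generator of part-annotated synthetic 3D objects,
    readers and writers for common point-cloud formats (OFF, PLY, XYZ,
    per-point part labels), the stimulus perturbations used in shape
    perception research (point-density downsampling, inversion, voxel
    "Lego" deformation, part scrambling), pure-R implementations of the
    DGCNN and Point Transformer classifiers with composable ablations
    (attention, position encoding, downsampling) and a downsampling
    intervention for DGCNN, a training loop with the standard point-cloud
    augmentations, experiment runners, and behavioural-comparison statistics
    (confusion matrices, off-diagonal confusion correlations, pooled
    accuracy-pattern correlations, and Steiger's test for dependent
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
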