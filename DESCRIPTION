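Package: histostack
Title: Three-Dimensional Reconstruction of Sparsely Sampled Whole-Mount
    Histology Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registers an ordered stack of two-dimensional whole-mount
    histology section images into a three-dimensional reconstruction.
    Implements tissue masking by Otsu thresholding, Reinhard-style stain
    normalization to a stack-median color space, enclosing-ellipse rigid
    initialization to a middle-reference frame, 180-degree flip resolution
    by global-feature cosine similarity, RANSAC rigid refinement from
    dense feature matches with iterative outward pairwise alignment,
    optional thin-plate-spline deformable refinement, resolution-scalable
    tile-streamed application of transforms to arbitrarily large images,
    and reconstruction-quality metrics (orientation accuracy, pairwise
    overlap, target registration error). A synthetic phantom generator
    with known ground truth makes the full pipeline testable without
    external data or pretrained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
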