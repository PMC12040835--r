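Package: delmar
Title: Deep Linear Matrix Approximate Reconstruction of Hierarchical Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multilayer ("deep linear") low-rank plus sparse matrix decomposition
    for resting-state fMRI, with an integrated multi-echo BOLD denoising first
    layer. Each layer factorises its input into a weight matrix, a spatial
    feature matrix and an L1-sparse background matrix by ADMM with
    soft-thresholding. Layer sizes and the number of layers are estimated
    automatically from the diagonal of a column-pivoted QR factorisation (a
    rank reduction operator). Includes NIfTI input/output with fixed voxel
    ordering, spatial-overlap and intensity similarity metrics with top-fraction
    binarisation, an intensity-weighted Hausdorff overlap metric, optimal
    component-template matching, test-retest matrices, intraclass correlation,
    and a synthetic multi-echo generator that plants a two-level network
    hierarchy with TE-linear BOLD amplitude and TE-independent noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
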