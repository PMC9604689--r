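Package: gubs
Title: Graph-Based Unsupervised Brain Segmentation of 3D MRI Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised skull stripping for T1-weighted head MRI. A 3D
    volume is represented as a 6-connected voxel adjacency graph weighted by
    absolute intensity differences; seed voxels sampled inside the brain, in
    the surrounding non-brain tissue and in the background are collapsed onto
    single representative nodes, and the minimum spanning tree of the
    collapsed graph is cut at the heaviest edge along the paths joining the
    representatives, yielding a three-class label volume. Includes NIfTI
    input/output, 3D morphological preprocessing, a synthetic head-phantom
    generator with ground truth, standard overlap metrics (Dice, Jaccard,
    sensitivity, specificity, accuracy, precision), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    RNifti,
    jsonlite,
    optparse,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
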