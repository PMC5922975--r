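Package: hydrabow
Title: Bag-of-Words Behavior Recognition and Motif Discovery for Hydra Videos
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An automated behavior-analysis pipeline for videos of the
    deformable cnidarian Hydra. Frames are segmented and registered to a
    canonical body pose, dense trajectories carrying HOF/HOG/MBH descriptors
    are extracted per body part, windows are encoded as power- and
    l2-normalized Fisher vectors over per-descriptor Gaussian-mixture
    codebooks, and behaviors are recognized with class-weighted RBF support
    vector machines (hard and soft multi-label rules) or discovered without
    supervision by t-SNE embedding, kernel density estimation and watershed
    segmentation of the behavioral space. An egestion detector flags rapid
    radial contractions from body-width dynamics, and a synthetic-video
    module generates deformable-animal fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    e1071,
    tiff,
    png,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr
biocViews: Classification, Clustering, Visualization, CellBasedAssays
Config/testthat/edition: 3
RoxygenNote: 7.3.3
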