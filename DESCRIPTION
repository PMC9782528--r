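Package: ClassDecomp
Title: Self-Supervised Class-Decomposition Transfer Learning for Irregular Image Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a backbone-agnostic pipeline for classifying image
    datasets that suffer from class imbalance, within-class multimodality and
    between-class overlap. Unlabelled images are embedded with a convolutional
    autoencoder and pseudo-labelled by density-based clustering (DBSCAN with a
    k-nearest-neighbour radius heuristic) to pretrain a small CNN on a
    self-supervised pretext task. Each downstream class is then decomposed into
    homogeneous sub-classes by affinity propagation over cosine similarities of
    PCA-reduced backbone features (with a fixed-k k-means baseline), the
    classifier is trained on the sub-class labels in shallow, fine or deep
    tuning modes, and sub-class probabilities are composed back to the original
    classes at prediction time. Grad-CAM heatmaps explain predictions at
    sub-class or composed-class level. A synthetic image generator with planted
    sub-cluster structure makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC
Config/testthat/edition: 3
biocViews: Classification, Clustering, DimensionReduction, FeatureExtraction
RoxygenNote: 7.3.3
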