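Package: NucleoMics
Title: Nuclear Morphometry and Multi-Omics Integration for Lung Cancer
    Subtyping and Survival Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for integrating nuclear morphometry
    extracted from H&E histology tiles with clinical, copy-number, somatic
    variant and mRNA expression tables for non-small-cell lung cancer.
    Provides tile preparation with histogram-matching stain normalization,
    a compact U-shaped encoder-decoder nucleus segmenter with an adaptive
    Otsu area/compactness quality filter, twenty per-nucleus color, shape
    (including the seven Hu moment invariants) and wavelet texture
    features, clinical and genetic factor encoding, per-patient dataset
    balancing and patient-level splitting, Pearson-correlation factor
    screening, and tuned classifier families (gradient boosted trees,
    random forest, adaptive boosting, feedforward network) with full
    metric reporting. A synthetic cohort generator with plantable subtype
    and survival signal makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    jsonlite,
    xgboost,
    randomForest,
    nnet,
    rpart
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Classification, FeatureExtraction, CellSegmentation,
    Survival, CopyNumberVariation, GeneExpression
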