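Package: raredrop
Title: Rare Circulating Plasma-Cell Detection, Phenotyping and Enumeration
    from Multichannel Immunofluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end liquid-biopsy analysis pipeline for rare
    circulating plasma cells in multiple myeloma and its precursor states.
    Provides a synthetic slide and cohort generator with full ground truth,
    nuclear and cellular segmentation with morphometric feature extraction
    from four-channel immunofluorescence frames (DAPI, CD138, BCMA, CD45),
    outlier-clustering rare-event detection in a PCA-reduced feature space,
    gradient-boosted curation of technical artifacts at a prediction
    confidence threshold, twelve-class marker phenotyping with membrane
    versus perinuclear BCMA localization, cells-per-mL enumeration, cohort
    comparison statistics (Wilcoxon rank sum, Spearman correlation, UMAP
    visualisation), and cross-validated patient-level disease-state
    prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    tiff,
    xgboost,
    randomForest,
    rpart,
    uwot,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    arrow,
    cluster,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
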