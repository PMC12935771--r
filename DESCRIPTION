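Package: histopet
Title: Voxel-Wise Comparison of Quantitative Histology and Tau PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable pipeline for voxel-to-voxel comparison of quantitative
    histological burden maps (phospho-tau, ferric iron, MAO-B) with tau PET
    standardized uptake value ratio (SUVR) images. Provides a seeded synthetic
    cohort generator (anatomical phantom, marker masks, classifier-like
    probability maps, section-to-blockface warps, and a PET volume generated
    from a known linear model), immunohistochemistry segmentation utilities
    with precision-recall/ROC threshold selection, percent-positive burden
    heatmaps with FWHM estimation and blur-to-FWHM resolution matching,
    thin-plate-spline landmark registration with Dice quality control, and a
    statistical layer of Spearman correlations, Wilcoxon rank-sum tests, and a
    fixed suite of nested linear models compared by AIC with variance
    inflation factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti,
    tiff,
    glmnet,
    optparse
Suggests:
    testthat (>= 3.0.0),
    car,
    EBImage
Config/testthat/edition: 3
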