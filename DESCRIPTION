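Package: iish
Title: Intra- and Inter-Site Radiomic Heterogeneity for Multi-Lesion CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies combined intra-site and inter-site tumor texture
    heterogeneity from multi-lesion CT studies. Computes per-voxel Haralick
    texture maps (energy, entropy, homogeneity, contrast) over a sliding
    patch, extracts texturally homogeneous subregions with kernel K-means
    and AIC model selection, summarizes pairwise subregion dissimilarities
    into a group dissimilarity matrix, and reduces it to the cluster
    dissimilarity (cluDiss) statistic. Also provides a 75-feature
    average-heterogeneity radiomics extractor (first-order, GLCM, GLRLM,
    GLSZM, NGTDM, NGLDM, Sobel and Gabor families), integrated
    radiomic-clinical-genomic risk scores with cut-point dichotomization,
    a SMOTE-balanced repeated cross-validation protocol for platinum
    resistance classification, scanner robustness and radiogenomic
    correlation screens, and a synthetic multi-lesion phantom generator
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    glmnet,
    pROC,
    survival,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
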