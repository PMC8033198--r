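Package: ceusomics
Title: Ultrasomics Texture Analysis and Diagnostic Modeling for
    Contrast-Enhanced Ultrasound of Focal Liver Lesions
Version: 0.1.0
Authors@R:
    person("CEUS", "Ultrasomics Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for machine-learning ultrasomics analysis
    of three-phase contrast-enhanced ultrasound (CEUS) image sets of focal
    liver lesions. Provides region-of-interest texture feature extraction
    (histogram, form factor, gradient, grey-level co-occurrence matrix and
    run-length matrix families; 1,044 features per image, 3,132 per patient
    triplet), redundancy/AUC/LASSO feature selection with the 1-SE rule,
    RBF-kernel support vector machine models built from ultrasomics features,
    a radiologist's ordinal score, or both, and a full diagnostic-performance
    evaluation suite (ROC/AUC, Youden operating point, DeLong and Wilcoxon
    comparisons, weighted kappa, ICC, decision curve analysis). Includes a
    synthetic three-phase lesion cohort generator so that the entire pipeline
    is testable without access to clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
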