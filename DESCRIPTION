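Package: hypoxrad
Title: Radiomic Surrogates of Tumor Hypoxia and Survival in Glioblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A radiogenomic analysis pipeline for glioblastoma that links
    compartment-specific MRI texture features to a transcriptomic hypoxia
    enrichment score and evaluates the selected radiomic markers as
    predictors of short-, mid-, and long-term overall survival. Provides
    per-pixel Laws energy, Gabor, and Haralick gray-level co-occurrence
    texture maps over necrotic, enhancing, and edematous tumor
    compartments on Gd-T1w, T2w, and FLAIR MRI; single-sample gene-set
    enrichment scoring of a 21-gene hypoxia signature; mutual-information
    feature selection under repeated stratified cross-validation;
    random-forest survival-group classification with Kaplan-Meier,
    log-rank, Cox proportional-hazards, and concordance-index evaluation;
    and a synthetic multi-contrast tumor-phantom cohort generator with a
    planted hypoxia-texture-survival chain so the full pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    randomForest,
    rlang,
    RNifti,
    stats,
    survival,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
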