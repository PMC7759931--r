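Package: ctradiomics
Title: CT Radiomic Texture Features and Circulating Tumor DNA Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline relating three-dimensional CT radiomic
    heterogeneity features to circulating tumor DNA mutant allele fraction
    (ctDNA maf) in longitudinal oncology cohorts. Provides LIFEx-style 3D
    feature extraction (histogram, shape, GLCM, GLRLM, GLZLM and NGLDM
    families) from masked Hounsfield-unit volumes, assembly of imaging visits
    with interpolated blood-derived maf and LDH, random-intercept linear
    mixed model screening with spiked-in random predictors and
    Benjamini-Hochberg FDR control, volume-adjusted likelihood-ratio
    screening, penalized and stepwise predictor selection for clustered data
    with random-predictor stopping rules, a PCA-derived radiomics signature,
    a correlation-matched Monte-Carlo null reference test, and quadratic
    mixed-model association analyses among maf, LDH and the signature.
    Includes a synthetic-data module generating phantom lesions and cohorts
    with the statistical structure the analysis assumes, so the full pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    glmnet,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
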