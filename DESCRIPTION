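Package: petrad
Title: PET/CT Radiomics and Deep-Learning Outcome Modelling for Head and
    Neck Cancer
Version: 0.1.0
Authors@R:
    person("petrad", "maintainers", email = "petrad@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for binary treatment-outcome prediction
    (overall and disease-free survival) from pre-treatment FDG PET/CT of
    head and neck squamous cell carcinoma. Provides a synthetic PET/CT
    phantom cohort generator with planted outcome effects; PET/CT
    preprocessing (soft-tissue CT windowing, SUV cut-off scaling, volume of
    interest cropping); the standard PET parameters SUV peak, metabolic
    tumor volume and total lesion glycolysis; a curated set of first-order,
    shape, GLCM, GLSZM, GLRLM and 3D local binary pattern radiomics
    features with brute-force oracles; repeated elastic net (RENT)
    stability feature selection including its brute-force repeated
    cross-validation frequency protocol; a model family spanning logistic
    regression, bagged forests, fully connected networks with and without
    explicit interactions, and a small 3D squeeze-excitation CNN; a nested
    cross-validation ensemble-averaging evaluation scheme with
    class-balanced bootstrap metrics; and VarGrad gradient-variance
    saliency with quantitative stratification by uptake, attenuation and
    tumor/node location.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
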