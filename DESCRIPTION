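Package: rectomics
Title: Rectal-Wall Radiomics for Timing Adaptive Prostate Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Longitudinal radiomics analysis of the rectal wall on planning CT
    and daily megavoltage CT images from prostate radiotherapy. Builds a
    2-pixel rectal-wall ring from rectum contours, tiles 8x8 subimages along
    it, extracts a 118-feature IBSI-style texture catalogue (first-order,
    GLCM, GLRLM, GLSZM, GLDZM, NGTDM, NGLDM), aggregates features to weekly
    time points, and fits elastic-net logistic regression models of grade >=1
    late rectal bleeding with bootstrap AUC evaluation to identify the
    earliest treatment week at which re-planning decisions are best informed.
    Includes a seeded synthetic phantom-cohort generator so the full pipeline
    is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Rcpp,
    RNifti,
    EBImage,
    glmnet,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
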