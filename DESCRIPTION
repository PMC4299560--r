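Package: ctild
Title: Quantitative CT Densitometry and Visual Scoring for Interstitial Lung Disease
Version: 0.1.0
Authors@R:
    person("ctild", "maintainers", email = "ctild@example.org", role = c("aut", "cre"))
Description: A tested pipeline for computer-aided quantification of
    interstitial lung disease from chest CT: threshold-based lung
    segmentation in Hounsfield-unit bands, density-mask fibrosis-fraction
    scoring with histogram descriptors (mean lung attenuation, skewness,
    kurtosis), the Warrick semiquantitative HRCT score, and the cohort
    statistics used to validate such scores (Pearson correlation with
    regression, two-way intraclass correlation, group comparisons, ROC
    analysis with a criterion table, exact binomial confidence intervals
    and Youden-optimal threshold selection). Includes generators for
    synthetic CT phantoms with known ground truth and synthetic patient
    cohorts with a prescribed correlation structure, so the whole pipeline
    is exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
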