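Package: bophmars
Title: Adaptive Regression Modeling of Biomarkers of Potential Harm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating biomarkers of potential harm (white blood
    cell count, urinary 8-epi-prostaglandin F2-alpha, urinary
    11-dehydro-thromboxane B2, and HDL cholesterol) to biomarkers of
    cigarette-smoke exposure and clinical covariates in large
    smoker/nonsmoker cohorts. Implements the full adaptive modeling
    workflow: below-limit-of-quantification handling, stratified median
    imputation and categorical encoding, ensemble-tree variable screening
    with nested predictor sets, multivariate adaptive regression splines
    with exact knot search and generalized cross-validation pruning,
    reparametrization of hinge bases into interpretable threshold (IFGT /
    IFLT) bases, ordinary least-squares refits with analysis/validation
    assessment, and marginal / delta R-squared variable-group importance.
    Includes a seeded synthetic cohort generator whose generating truth is
    a set of published threshold-basis models, so the entire pipeline is
    testable without access to proprietary study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ranger,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
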