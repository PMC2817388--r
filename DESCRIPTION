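Package: flowtrees
Title: Tree-Based Discovery of Flow Cytometry Correlates of a Binary
    Clinical Endpoint
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening percent-of-gated flow-cytometry cell-subset
    variables against a binary clinical endpoint such as CD4 T-cell recovery
    on antiretroviral therapy.  Implements the full discovery workflow:
    median dichotomization with single-value imputation, univariate
    contingency screening with odds ratios, chi-square tests and false
    discovery rate adjustments, classification trees with Gini splitting and
    weakest-link cost-complexity pruning, random forests with out-of-bag
    permutation and impurity-decrease variable importance, and logic
    regression over Boolean trees fitted by simulated annealing.  A
    compositional flow-panel simulator with planted outcome signals supports
    method evaluation when trial data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    randomForest,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
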