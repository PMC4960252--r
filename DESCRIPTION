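Package: metabselect
Title: Variable Selection for Untargeted LC-MS Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three complementary variable-selection workflows for two-class
    untargeted LC-MS metabolomics feature tables: OPLS-DA with VIP scoring,
    OPLS-DA on an FDR-pre-filtered feature set, and LASSO penalized logistic
    regression with bootstrap stability selection.  Includes the standard
    pooled-QC quality-assurance filtration chain (QC presence, QC coefficient
    of variation, group presence), unit-variance and Pareto scaling, PCA
    screening with Hotelling's T-squared outlier limits, and a synthetic
    feature-table generator with known ground truth for benchmarking the
    three approaches against each other.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
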