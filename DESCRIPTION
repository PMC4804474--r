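Package: mctwo
Title: Two-Step Feature Selection by Maximal Information Coefficient
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Feature selection for binary-labelled "large p, small n"
    expression data. A first filtering stage screens features by their
    maximal information coefficient (MIC) with the class label and removes
    features dominated by a more label-relevant, more strongly associated
    feature; a second wrapper stage runs a best-first search over the
    surviving candidates, scoring subsets by the leave-one-out balanced
    accuracy of a 1-nearest-neighbour classifier. Also provides t-test,
    Wilcoxon and ROC-AUC baseline rankers, downstream classifier adapters,
    internal and external cross-validation harnesses with win/tie/loss
    comparison triplets and the EI accuracy-complexity index, and a
    synthetic-data generator with planted informative, redundant and noise
    features. The MIC estimator ships two backends: the standard
    equipartition + dynamic-programming approximation and an exhaustive
    grid-enumeration oracle for small sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    rlang,
    tibble,
    dplyr,
    readr,
    generics,
    ggplot2,
    jsonlite,
    e1071,
    rpart,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
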