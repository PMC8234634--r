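Package: radbench
Title: Simulation Benchmark of Classifiers and Feature Selection for
    Radiomic Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates synthetic radiomic-like feature cohorts with
    controlled correlation structure, skewness and kurtosis via the
    Fleishman power transformation and the Vale-Maurelli intermediate
    correlation construction, plants outcome signal on designated control
    features, and benchmarks six classifiers crossed with six feature
    selection strategies on AUC, sensitivity, specificity and
    planted-feature recovery across a factorial of sample size, outcome
    balancing and signal strength.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    Matrix,
    class,
    e1071,
    glmnet,
    ranger,
    stats,
    utils,
    xgboost
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
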