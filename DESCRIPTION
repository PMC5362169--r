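Package: lupusrnn
Title: Recurrent Neural Networks for Predicting Chronic Damage Accrual in
    Systemic Lupus Erythematosus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal analysis pipeline for predicting the onset of
    irreversible organ damage (SLICC/ACR Damage Index progression) in
    systemic lupus erythematosus cohorts from sequences of clinic visits.
    Implements an Elman-style recurrent network trained by stochastic
    gradient descent with backpropagation through time and a training-AUC
    early-stopping rule, pooled eight-fold cross-validated ROC analysis
    with operating-threshold reporting, static feedforward and logistic
    baselines on concatenated visit windows, case/control eligibility
    filtering with a rare-feature cutoff, descriptive cohort statistics,
    and a discrete-time hazard simulator of synthetic visit histories for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    yaml,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
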