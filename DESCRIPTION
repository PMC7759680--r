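Package: cfgan
Title: Individualized Treatment Effects via Counterfactual Generative
    Adversarial Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates individualized treatment effects (ITEs) from tabular
    observational data with a two-block conditional generative adversarial
    network: an imputation block whose generator fills in unobserved
    counterfactual outcomes against a discriminator that tries to identify
    the factual component, and an ITE block that learns the conditional
    distribution of the full potential-outcome vector.  A treatment
    assignment indicator and a treatment quantity vector extend the approach
    to binary, categorical and continuous (dosed) treatments.  Includes
    LASSO-based biomarker selection for treatment-effect prediction and
    optimal treatment choice, Garson importance for trained networks, seeded
    simulation designs with retained ground-truth counterfactuals, a
    per-arm (T-learner) baseline harness and the associated evaluation
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils,
    class,
    e1071,
    FNN,
    ranger
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    pROC,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
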