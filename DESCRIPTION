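Package: sdgaudit
Title: Auditing Hallucinations and Downstream Utility of Tabular Synthetic Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify hallucinations in tabular synthetic health data
    and their impact on downstream prognostic modelling. Simulates reference
    populations with core and adjunct variables, builds population variants of
    graded structural complexity, fits sequential decision-tree and Chow-Liu
    Bayesian-network synthesizers (with a plugin contract for other generator
    families), identifies hallucinated records by exact-match antijoin against
    the population variant, measures train-synthetic-test-real (TSTR) and
    train-real-test-real (TRTR) AUROC with gradient-boosted trees and a small
    multilayer perceptron, and estimates the complexity-to-hallucination-rate
    and hallucination-rate-to-utility effects with random-intercept
    mixed-effects models including Nakagawa marginal and conditional R2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    rpart,
    igraph,
    lme4,
    xgboost,
    jsonlite,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    arrow,
    optparse
Config/testthat/edition: 3
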