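Package: comparatornoise
Title: Effect of Comparator Misclassification on Apparent Diagnostic Test
    Performance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and closed-form analysis of how classification noise
    in an imperfect reference standard ("comparator") degrades the apparent
    performance of a diagnostic test. Generates synthetic cohorts (perfectly
    separated, binormal, or fixed sensitivity/specificity), injects comparator
    misclassification under uniform, class-specific, or uncertainty-weighted
    schemes, and summarises apparent AUC, positive/negative percent agreement,
    and predictive values as medians with empirical confidence intervals over
    repeated noise injections. Includes closed-form expectations for apparent
    metrics and the maximum attainable AUC under a given misclassification
    rate, exact-binomial rejection probabilities for very-high-performance
    requirements, and an expert-panel adjudication model that derives
    per-patient classification confidence and misclassification rates from
    three panelist calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
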