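Package: stratcost
Title: Micro-Costing of Risk-Stratified Breast Cancer Screening Strategies
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A bottom-up costing pipeline for risk-stratification strategies
    offered at a woman's first mammography screen: a decision-pathway
    expected-cost engine with per-stage breakdowns for three strategies
    (risk questionnaire; adding automated breast-density measurement; adding
    a 142-SNP polygenic test) in trial and routine health-service settings,
    deterministic and probabilistic (Monte Carlo) sensitivity analyses with
    centile-based pseudo confidence intervals, a batch-size step-cost model
    for array genotyping, and national-rollout and value-of-implementation
    calculators. Ships a fully documented parameter fixture and seeded
    synthetic-model generators so every component is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
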