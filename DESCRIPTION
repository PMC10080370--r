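Package: psortransit
Title: Transition-Diagram Modelling of Posttreatment Psoriasis Severity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates posttreatment prognosis of psoriasis skin lesions as
    transition probabilities among four Investigator's Global Assessment (IGA)
    severity stages over two follow-up windows (0-1 month and 1-12 months).
    Implements the full observational-cohort pipeline: multiple imputation of
    baseline covariates by chained equations with predictive mean matching,
    tri-directional 1:1 nearest-neighbour matching with replacement on
    Mahalanobis distance, frequency-weighted transition-matrix estimation with
    last-observation-carried-forward outcomes, Rubin-rule pooling across
    imputations with 95 percent confidence intervals, and between-therapy
    contrasts. Ships a confounded synthetic-cohort generator with serialized
    ground truth so every stage is testable without access to registry data,
    plus Graphviz DOT transition-diagram export and a reproducible pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'reference.R'
    'AllGenerics.R'
    'AllClasses.R'
    'simulate.R'
    'impute.R'
    'match.R'
    'transitions.R'
    'pool.R'
    'report.R'
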