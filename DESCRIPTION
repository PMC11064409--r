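Package: pheindex
Type: Package
Title: Rule-Based Digital Phenotyping of Children at Risk for Rare Genetic Disorders
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the PheIndex digital phenotyping algorithm for
    structured pediatric electronic medical records: thirteen rule-based
    criteria evaluated over encounter, diagnosis, procedure and lab-order
    tables for children from birth to three years of age, combined into an
    integer severity score and a binary classification flagging children at
    increased risk for rare genetic disorders. Also provides cohort-level
    analytics (per-criterion frequencies, term-stratified Jaccard
    co-occurrence matrices, time-to-first-criterion curves, score
    distributions), diagnostic-validation computations (confusion summaries
    with unknown-label exclusion, prevalence-adjusted positive predictive
    value, per-criterion accuracy, stratified chart-review sampling), a
    configurable vocabulary layer for ICD code sets and procedure keyword
    rules, a synthetic EMR cohort generator with latent disorder status and
    controllable documentation noise, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
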