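Package: htncea
Title: Markov Cohort Cost-Effectiveness Analysis of Hypertension Care
    Strategies in Rural Kenya
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seven-state Markov cohort model for the cost-effectiveness of
    community-based hypertension care strategies (usual care, group medical
    visits, microfinance, and their combination) in rural Kenya. Converts
    QRISK3 ten-year cardiovascular risk into annual transition probabilities
    under a constant-hazard assumption, adjusts recurrent-event risk with
    hazard ratios, accrues discounted costs and disability-adjusted
    life-years with half-cycle correction, ranks strategies on the
    cost-effectiveness frontier with extended dominance, and quantifies
    uncertainty with one-way deterministic sensitivity analysis, threshold
    analysis, and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves. Includes a synthetic
    individual-level cohort generator and an independent microsimulation
    oracle for validating the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
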