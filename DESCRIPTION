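Package: bloomnet
Title: Plant-Flower-Visitor Network Analysis for Agrochemical Field Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds plot-level weighted bipartite plant-insect visitation
    networks from long-format interaction records, computes structural
    metrics (connectance, degrees, NODF nestedness, size-corrected NODFc,
    Barber's weighted bipartite modularity), standardizes them against
    fixed-margin Patefield null ensembles as z-scores, estimates Hill-number
    diversity with sample coverage and rarefaction, and tests agrochemical
    treatment effects with block-random-effect linear mixed models including
    marginal and conditional R-squared. Includes a synthetic-experiment
    generator emulating a randomized block design (fertilizer, herbicide,
    combination, control) so the full pipeline runs without field data, and
    the agrochemical dose arithmetic for the application schedule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
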