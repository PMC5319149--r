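Package: gd1markov
Title: Markov Cohort Projection of Long-Term Outcomes in Treated Gaucher
    Disease Type 1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A DS3-based framework for projecting long-term outcomes of
    patients starting treatment for Gaucher disease type 1. Defines nine
    ranked health states from DS3 severity categories and bone involvement,
    computes health-state utilities from a generalized-estimating-equation
    regression by recycled predictions, derives annual transition probability
    matrices from a proportional-odds (ordered logistic) model, calibrates a
    Gompertz disease-specific mortality curve to published life expectancies
    and splices it with a general-population life table, and runs an annual
    Markov cohort simulation producing discounted and undiscounted
    quality-adjusted life years and state-occupancy profiles. Includes
    estimation routines with cluster-robust standard errors and a synthetic
    longitudinal panel generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    sandwich,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
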