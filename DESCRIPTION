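Package: thyronod
Title: Microsimulation of Thyroid Nodule Natural History, Detection and
    Calibration
Version: 0.1.0
Authors@R:
    person("Model", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Individual-level annual-cycle microsimulation of benign and
    malignant thyroid nodule natural history in women. Nodules follow
    closed-form volume trajectories (logistic growth towards a fixed
    carrying capacity, exponential shrinkage, or linear stability), are
    initiated at age-dependent rates, and become clinically detected at a
    rate linear in the volume of the largest nodule. Unknown age-stratified
    parameters (development rates, lognormal growth-rate distributions and
    detection coefficients) are estimated by simulated annealing with
    greedy refinement of archived local minima against binned incidence
    and size-at-detection targets under a weighted chi-squared goodness of
    fit. Includes a cross-sectional screening analysis of the subclinical
    nodule reservoir, synthetic fixture generators (life table,
    longitudinal tumor-diameter records, calibration targets), and
    longitudinal kinetics estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
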