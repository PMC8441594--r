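Package: htncea
Title: Lifetime Cost-Effectiveness Modelling of Multicomponent Hypertension Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A Markov cohort state-transition model for the lifetime
    cost-effectiveness of a community-health-worker-led multicomponent
    hypertension control programme versus usual care in a low-income
    Argentine primary-care setting. Implements a three-state (low CVD risk,
    high CVD risk, death) cohort model with one-year post-event tunnel
    states, Framingham 10-year general-CVD risk stratification, scenario
    based extrapolation of the trial blood-pressure effect, half-cycle
    corrected discounted cost and QALY accounting, one-way (tornado)
    sensitivity analysis, second-order Monte Carlo probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves, a
    patient-level microsimulation oracle, and a synthetic trial-panel and
    life-table generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
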