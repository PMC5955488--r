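Package: povdyn
Title: Age-by-State Markov Models of Poverty Dynamics and Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how crossing an income threshold shapes
    cohort structure and mortality disparities over the life course.
    Estimates age- and state-specific annual survival and poverty
    entry/exit probabilities from longitudinal panel surveys by pooled
    weighted logistic regression, assembles the age-by-state block
    transition matrix, and derives cohort state structure, remaining
    life expectancy and its variance from the absorbing-chain
    fundamental matrix, together with stochastic simulation of
    individual lifetime trajectories. Includes a synthetic panel
    generator with known logit-scale ground truth so the full pipeline
    is testable without restricted survey data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
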