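Package: mineralize
Title: Respirometry-Based Analysis of Hydrocarbon Biodegradation in Soil
    Microcosms
Version: 0.1.0
Authors@R:
    person("R.", "Walker", email = "rwalker@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing aerobic hydrocarbon biodegradation
    experiments measured by alkaline-trap respirometry. Converts NaOH-trap
    back-titration records into daily and cumulative CO2 production with
    control-baseline subtraction, reconstructs remaining-substrate
    trajectories from CO2 stoichiometry, estimates piecewise first-order
    degradation rate constants by exhaustive breakpoint search, assembles
    endpoint carbon mass balances (mineralized, residual diesel-range
    organics, nitrogen-derived biomass, volatilization allowance,
    unaccounted), and compares treatments with paired t-tests and one-way
    ANOVA with Tukey HSD. Includes a seeded synthetic microcosm generator
    that emulates soil-bed and suspended-grid fuel-degradation experiments
    so the full pipeline is testable without laboratory data.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
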