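Package: phacksim
Title: Evolutionary Agent-Based Simulation of P-Hacking and Significance
    Thresholds
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a population of researchers who trade effort for
    productivity, test one or more hypotheses per experiment with simulated
    two-sample t-tests, publish any nominally significant result, and evolve
    their methods through selective replacement.  Experiments draw true
    Cohen's d effect sizes from an exponential prior, test statistics from
    the noncentral t distribution, and adjudicate simulated truth with the
    Sidak correction, so the published false-positive rate of the simulated
    literature can be tracked as the significance threshold is moved from
    0.05 to 0.005.  Includes closed-form calculators (effect-size scale from
    the null prior, the analytic literature false-positive rate from prior
    odds and power), replicated scenario grids with deterministic seeding,
    trajectory and histogram summaries, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
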