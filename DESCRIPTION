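Package: drivesim
Title: Stochastic Simulation of CRISPR Homing Gene Drive Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time, allele-level simulation of a CRISPR homing gene
    drive spreading through a large randomly mating population. Each discrete,
    nonoverlapping generation cycles through diploid zygote formation with
    inbreeding, super-Mendelian homing conversion of susceptible alleles,
    selection against drive carriers with tunable dominance and exposure, and
    Wright-Fisher binomial genetic drift, in either stochastic (binomial-draw)
    or deterministic (expectation-propagation) mode and with pre- or
    post-zygotic homing. Trajectories are classified into fixation, loss,
    temporary, and equilibrium outcomes, and a Monte Carlo sensitivity
    framework samples the design variables (conversion efficiency, resistance
    level and frequency, fitness cost, exposure, dominance, inbreeding),
    tabulates outcome frequencies, builds balanced per-outcome datasets, and
    fits within-outcome regressions of the drive's frequency dynamics on the
    design variables. A command-line interface is included for shell use.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
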