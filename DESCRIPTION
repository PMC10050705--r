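Package: mtflow
Title: One-Dimensional Pulse-Wave Haemodynamics and Mechanical Thrombectomy Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates blood flow in networks of elastic arteries with a
    second-order MUSCL finite-volume solver for the one-dimensional
    pulse-wave equations, with three-element windkessel outlets,
    characteristic-based junction coupling, and convergence to a periodic
    steady state. Generates ageing virtual populations by scaling a baseline
    arterial network from published age-dependent distributions and filtering
    on brachial pressure plausibility, and simulates mechanical thrombectomy
    scenarios (balloon guide catheter, aspiration catheter at several sites
    and rates, moving clot as a stenosis) with haemodynamic post-processing
    of cerebral flows, velocities and pulsatility indices.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
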