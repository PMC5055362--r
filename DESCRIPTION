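Package: ptsdflow
Title: Stock-and-Flow Simulation of PTSD Among Military Personnel and
    Veterans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A system-dynamics (stock-and-flow) model of the population
    of US military personnel and veterans affected by post-traumatic
    stress disorder.  Six population stocks (healthy, ill-undiagnosed
    and ill-diagnosed, in the military and post-military sectors, with
    the diagnosed-veteran stock split into a recent and a pre-2000
    cohort) are connected by nine pathways and integrated forward in
    time by an explicit Euler scheme with flow capping.  The package
    provides partial-model calibration of unknown fractional rates to
    historical time series, war-scenario and policy-intervention grids
    with healthcare-cost projection, Latin-hypercube sensitivity
    sweeps, a steady-state war-pulse counterfactual that measures
    system inertia, packaged historical fixtures, a synthetic-history
    generator, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
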