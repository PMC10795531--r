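Package: adm1sim
Title: Coupled Anaerobic Reactor and Biochemical Methane Potential
    Simulation with the ADM1/BSM2 Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the Benchmark Simulation Model 2 (BSM2) variant of the
    IWA Anaerobic Digestion Model No. 1 (ADM1) as a coupled two-stage
    simulator: a continuous anaerobic reactor (CSTR) whose steady-state
    output seeds a batch biochemical methane potential (BMP) assay reactor.
    Provides the full biochemical kinetic core (disintegration, hydrolysis,
    Monod uptake with pH, hydrogen and free-ammonia inhibition), acid-base
    chemistry in both differential (ODE) and algebraic (DAE) formulations,
    gas-liquid transfer and headspace dynamics, weighted least-squares
    calibration of influent sludge composition by differential evolution
    (DE/rand/1/bin), and residence-time stratification optimization of
    methane production. Includes BMP assay data handling and a synthetic
    replicate-curve generator for testing inverse procedures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
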