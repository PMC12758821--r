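Package: glucohr
Title: Nocturnal Glucose-Heart-Rate Coupling: Simulation, Fitting and Risk Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-state ordinary differential equation model coupling
    nocturnal plasma glucose with resting heart rate, aimed at wearable-sensor
    (continuous glucose monitor and heart-rate tracker) data. Provides the
    coupled ODE system with a Gaussian dawn-phenomenon input and its adaptive
    Dormand-Prince integration, equilibrium and local stability analysis of the
    autonomous system, synthetic nocturnal data generation with Poisson
    measurement noise, a preprocessing pipeline for raw timestamped exports
    (night-window extraction, gridding, across-night averaging,
    Savitzky-Golay smoothing), bounded particle swarm optimization for
    parameter estimation, Latin-hypercube/partial-rank-correlation global
    sensitivity analysis, and a weighted metabolic risk score with categorical
    stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    signal,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
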