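Package: apswarm
Title: Particle Swarm Fitting of Phenomenological Cardiac Action
    Potential Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates two- to four-variable phenomenological cardiac
    action potential models (Mitchell-Schaeffer, modified
    Mitchell-Schaeffer, modified FitzHugh-Nagumo, Fenton-Karma,
    Bueno-Orovio-Cherry-Fenton and a Brugada-phenotype variant) under
    periodic pacing protocols, and fits their parameters to voltage
    time-series and/or action potential duration data with a
    constriction-coefficient particle swarm optimizer.  Batch forward
    Euler integration of thousands of candidate parameter sets runs in
    compiled code with runtime SIMD dispatch.  Includes a synthetic-data
    generator for parameter-recovery studies and tools for repeated-fit
    identifiability analysis (normalized parameter distributions,
    standard-deviation comparisons and per-parameter two-sample tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
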