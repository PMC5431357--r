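Package: loopwave
Title: Stochastic Birth-Death-Migration Dynamics and Emergent Waves on
    Loop Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a continuous-time stochastic
    birth-death-migration process on directed loop networks, in which
    coherent rotating waves emerge from purely incoherent, memoryless
    particle dynamics.  Provides an exact (Gillespie) stochastic
    simulator, a truncated master-equation solver that serves as a
    ground-truth oracle at small population sizes, the deterministic
    mean-field system including piecewise-smooth sliding dynamics on the
    simplex boundary, numerical limit-cycle computation (wave frequency
    and amplitude versus the control parameter), the critical parameter
    above which the wave state cannot exist, and classifiers that label
    stochastic trajectories as amorphous, wave, intermittent or
    collapsed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
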