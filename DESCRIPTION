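Package: doppelsim
Title: Doppelganger Brownian-Dynamics Simulations for Single-Particle
    Tracking Nanorheology
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing intracellular nanoparticle tracking data
    and for running "doppelganger" stochastic simulations that replicate an
    experiment's track statistics particle-for-particle.  Provides trajectory
    input/output and filtering, time-averaged mean-squared-displacement (MSD)
    analysis with power-law fitting and bootstrap confidence intervals,
    velocity autocorrelation, fixed-timestep Brownian dynamics inside
    rectangular cells under four models of cytoplasmic viscosity
    heterogeneity (uniform, spatial, cellular, combined), model calibration
    against summary statistics, nested analysis-of-variance variance
    decomposition, log-space spread statistics (fold ranges), Levene and
    rank-sum comparisons, and ergodicity-breaking diagnostics comparing
    ensemble- and time-averaged MSDs.  A synthetic-experiment generator makes
    every downstream module testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
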