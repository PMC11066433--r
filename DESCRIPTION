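Package: tgfswitch
Title: Bistable TGF-beta-1 Switch Models of Dermal Fibroblast Senescence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic and stochastic models of the TGF-beta-1 /
    thrombospondin-1 (THBS1) / fibromodulin (FMOD) regulatory switch that
    governs dermal fibroblast senescence. Provides the core and endogenous
    steady-state ordinary differential equation models with fixed-point
    finding and stability classification, saddle-node (fold) detection and
    one- and two-parameter bifurcation scans, an Ornstein-Uhlenbeck
    stochastic extension simulated by the Euler-Maruyama scheme with a
    Silverman critical-bandwidth multimodality test, nonlinear least-squares
    estimation of the dose-response and population-doubling-level models, a
    reduced mechanistic TGF-beta / VEGF crosstalk network with differential
    evolution calibration, finite-difference sensitivity analysis and
    in-silico interventions (washout, timed kinase inhibition, knockdown),
    and seeded synthetic-data generators for every input the analyses
    consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
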