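Package: musycr
Title: Mass-Action Dose-Response Surfaces and Multi-Dimensional Drug Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies two-drug combination pharmacology with the MuSyC
    formalism: a four-state mass-action state-transition model whose steady
    state is a two-dimensional Hill dose-response surface with decoupled
    synergy parameters for potency (alpha), efficacy (beta) and
    cooperativity (gamma). Provides a staged bounded nonlinear least-squares
    fitting pipeline seeded by monotherapy Hill fits, Monte-Carlo percentile
    confidence intervals, quality-control filters, a checkerboard-surface
    simulator, and reference synergy scores (Bliss, Loewe, highest single
    agent, Chou-Talalay combination index) together with diagnostics for the
    Hill-slope and efficacy-range biases those classical metrics carry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
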