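Package: aestheval
Title: Stochastic Reinforcement Learning of Aesthetic Values
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a motivation-gated delta-rule
    model of how aesthetic values form. Sensory inputs (visual balance and
    complexity) are drawn from a truncated bivariate Gaussian on the unit
    square, rewards are stochastic with zero-mean structure over the input
    range, and a motivation function of complexity gates both reward and
    learning. Provides the discretized learning loop, quadrature-based
    fixed-point and error-landscape analysis, weight-redundancy geometry,
    value landscapes with peak-shift (value-exaggeration) diagnostics, and
    scripted experiments for learning dynamics, error descent, competition
    ablations, individuality sweeps, and value probes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
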