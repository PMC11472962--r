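Package: coaddiction
Title: Smoking-Alcohol Dual Addiction Dynamics, Optimal Control and
    Cost-Effectiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic compartmental model of the joint spread of smoking
    and alcohol addiction in a community, with eleven behavioural compartments
    and standard-incidence forces of addiction. Provides addiction-free and
    endemic equilibria, closed-form and next-generation-matrix effective
    reproduction numbers, Routh-Hurwitz and eigenvalue stability assessment,
    backward-bifurcation diagnosis via numeric centre-manifold coefficients,
    normalized forward sensitivity (elasticity) indices, a six-control
    Pontryagin optimal-control problem solved by a fourth-order Runge-Kutta
    forward-backward sweep over a catalogue of nine intervention strategies,
    and incremental cost-effectiveness ratio (ICER) ranking with iterative
    dominance elimination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
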