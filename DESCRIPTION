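Package: visuotrack
Title: Optimal-Control Modeling of Visuomotor Compensatory Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis of visuomotor compensatory tracking
    behavior under the assumption that subjects act as noisy
    linear-quadratic-Gaussian (LQG) optimal controllers. Provides a small
    continuous-time linear-systems toolbox (interconnection, Pade delay
    approximation, Riccati and Lyapunov solvers, balanced Hankel singular
    values, frequency response, zero-order-hold discretization), assembly of
    the nine-state tracking plant and synthesis of the corresponding LQG
    controller from four subject parameters (response latency, endogenous
    noise intensity and bandwidth, and a combined control-cost/multiplicative
    noise weight), a synthetic-cohort generator that reproduces the trial
    protocol, a model-free cross-correlation latency estimator, per-trial
    frequency-domain model fitting by Nelder-Mead, effort/performance Pareto
    front construction, controller-complexity analysis via Hankel singular
    values, and cohort-level statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    signal,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
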