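Package: qcbao
Title: Beam-Angle Optimization for Proton Therapy via ADMM with a QUBO
    Beam-Selection Subproblem
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves the joint beam-angle selection and proton spot-intensity
    optimization problem (beam-angle optimization, BAO) formulated as a mixed
    integer program.  The solver splits the problem with an augmented
    Lagrangian (ADMM): spot intensities are updated by weighted least squares
    with iterative convex relaxation of dose-volume-histogram constraints,
    minimum-monitor-unit feasibility is enforced through a proximal soft
    threshold, and the binary beam-selection subproblem is assembled as a
    quadratic unconstrained binary optimization (QUBO) solved by exhaustive
    enumeration, simulated annealing, or a genetic algorithm.  Includes a
    synthetic phantom generator with an analytic Bragg-peak pencil-beam dose
    model so the full pipeline is testable without clinical data, plan-quality
    metrics (conformity index, DVH, Vx), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
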