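Package: fibreops
Title: Muscle Fibre Operating Ranges from Hill-Type Musculoskeletal Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for delimiting muscle fibre operating ranges on the active
    force-length curve from Hill-type muscle-tendon models of a limb.
    Provides muscle-tendon unit parameterization (maximal isometric force
    from belly mass and optimal fibre length, dimensionless tendon stiffness,
    allometric scaling of activation time constants, first-approximation
    tendon slack lengths), smooth differentiable Hill characteristic curves
    with tendon force as the contraction state, a multi-trial inverse
    (muscle-redundancy) solver that estimates muscle excitations from joint
    kinematics and external joint moments while tuning optimal fibre length
    and tendon slack length through shared factors, a static posture battery
    that circumscribes viable fibre operating ranges over randomly sampled
    limb poses with explicit viability filters, and post-processing analyses
    (operating-range summaries, force-length region classification,
    hyperplane linearity fits, and fibre/MTU range decoupling regressions).
    A synthetic-data module generates toy limb models and gait trials with
    known ground truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    deSolve,
    signal,
    pracma,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
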