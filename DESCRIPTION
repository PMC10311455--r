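Package: kneephantom
Title: Knee-Exoskeleton Testing with a Two-Link Lower-Limb Mechanical Phantom
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and inverse-dynamics analysis of a two-link
    lower-limb mechanical phantom used to bench-test passive knee exoskeletons.
    Generates child-gait knee trajectories, drives the phantom geometry,
    applies a torsional-spring exoskeleton model with optional soft-tissue
    (brace) compliance and viscous losses, and emits synthetic marker and
    load-cell recordings. The analysis chain mirrors a standard motion-capture
    pipeline: zero-phase Butterworth filtering, spline resampling, joint-center
    estimation, finite-difference kinematics, a per-sample six-equation
    Newton-Euler solve for the knee assistance moment, and work-loop metrics
    (assistance stiffness, engagement offset, hysteresis) plus torsional-spring
    bench characterization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
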