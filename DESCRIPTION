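Package: mupool
Title: Multi-Motor-Unit Muscle Pool Simulation and Force-Matching Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates force production by muscles modelled as pools of
    hundreds of rate-coded motor units. Provides nine pool variants combining
    exponential, strength-matched and mixed recruitment-threshold functions
    with linear and logarithmic rate-coding functions and three maximum
    firing-rate schemes; converts neural drive to excitation impulse trains
    with a discrete-time timing correction; maps impulse trains to activation
    through calibrated third-order twitch dynamics with tetanic
    normalization; and combines per-unit forces under a Hill-type
    force-velocity-length gain. Includes a feedforward (plus optional
    idealized feedback) neural-drive controller fitted by a two-stage
    mixed-integer genetic algorithm and Nelder-Mead procedure against
    elementary force tasks, task generators (parabolic elementary tasks,
    isometric trapezoids, seeded synthetic reaching fixtures), steady-state
    drive-to-force maps, and force-matching error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    deSolve
Config/testthat/edition: 3
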