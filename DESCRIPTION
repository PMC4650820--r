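Package: mkmcortex
Title: Two-Layer Multiplex Kuramoto Dynamics of Cortical Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-layer multiplex Kuramoto model of interacting
    cortical regions, in which an excitatory-excitatory layer carries plain
    sinusoidal phase coupling and an excitatory-inhibitory layer carries
    Sakaguchi-shifted coupling, the phase shift encoding an inhibitory
    synaptic delay. Provides the underlying delay-coupled Wilson-Cowan
    network dynamics so the phase-reduction equivalence can be checked
    numerically, order parameters (Kuramoto order parameter, largest
    Lyapunov exponent by the twin-trajectory method, stationary mean
    frequency deviations), a (coupling, phase-shift) phase-diagram sweep
    with classification into unsynchronized, synchronized and chaotic
    regimes, and critical-coupling location by bisection. Includes
    Erdos-Renyi multiplex network construction, edge-list serialization,
    reproducible seeded sweeps and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    withr,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
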