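Package: spindlesim
Title: Biophysical Muscle-Spindle Simulation with Intrafusal Cross-Bridge
    Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the receptor potential of a muscle-spindle Ia
    afferent from the cross-bridge dynamics of two intrafusal fibres, a
    dynamic bag1 fibre and a static bag2/chain fibre. Each fibre is a
    half-sarcomere with two-state (attached/detached) myosin kinetics
    resolved over a cross-bridge strain grid, coupled to calcium-driven
    thin-filament activation with inter-filament cooperativity. Includes
    generators for ramp-and-hold, paired triangular and sinusoidal stretch
    protocols, extraction of classical spindle response features (initial
    burst, dynamic response, dynamic index, force-recovery time), and sweep
    drivers for studying history dependence of the stretch response.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
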