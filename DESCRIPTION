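Package: rockersim
Title: Flow, Shear Stress and Thermal Simulation for Rocking Biofilm Incubators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the free-surface flow inside a rectangular culture-plate
    well mounted on a seesaw rocking platform, and turns the results into the
    quantities biofilm researchers care about: wall shear stress maps over
    rocking speed, rocking/wavefront resonance predictions, laminar pipe-flow
    equivalences for clinically relevant scenarios (catheters, hemodialysis
    lines, drinking-water pipes), wavefront velocity estimation at the channel
    center, and a lumped-parameter Peltier/PID thermal control simulation with
    thermistor conversion. The flow model is a well-balanced finite-volume
    shallow-water solver with wetting and drying on the tilting channel floor,
    with a laminar parabolic-profile closure for the wall shear stress.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
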