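Package: mstpath
Title: Simultaneous Heading and Path-Curvature Perception from Optic Flow
    in a Model of Primate MSTd
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a three-stage neural model (V1, MT, MSTd) of visual
    self-motion perception. Synthetic random-dot scenes and parametric
    observer trajectories generate first-order optic flow, which is
    spatially pooled, compared against a bank of spiral motion-pattern
    templates, and fed into a shunting recurrent competitive network whose
    most active unit encodes path curvature (through its spirality) and
    heading (through the visuotopic position of its center of motion).
    Includes scripted in-silico psychophysics protocols: circular-path
    travel under five gaze conditions, smooth-pursuit conditions with an
    extra-retinal gain field, the simulated-rotation heading illusion,
    competition lesion studies, dot-density sweeps, and a circular-sled
    paradigm probing path-selective responses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
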