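Package: fescycle
Title: Kinematic Modelling and Stimulation Pattern Design for Rat FES Cycling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Solves the one-degree-of-freedom closed kinematic chain of a rat
    hindlimb pedaling a stationary bicycle, computing hip, knee and ankle
    angles, joint-velocity transforms and torque-transfer ratios as functions
    of crank angle.  Translates the torque-transfer profiles into functional
    electrical stimulation (FES) switching patterns for four muscle groups or
    for the femoral and sciatic nerves, in both pedaling directions and for
    both legs.  Provides exact arc-set algebra on the crank circle, estimation
    of experimental regions of activity (RoA) from stimulation-trial tables,
    angular confusion measures with sensitivity, specificity, PPV and NPV, and
    a seeded synthetic-trial generator that emulates the nerve-mapping
    protocol so the full validation pipeline runs without animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
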