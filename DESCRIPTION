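Package: balancefb
Title: Identification of Delayed Center-of-Mass Feedback in Perturbed Standing and Walking
Version: 0.1.0
Authors@R: person("Balance", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to identify the sensorimotor transformation behind the ankle
    balance strategy. Estimates delayed linear feedback gains from
    center-of-mass (or ankle-joint) kinematics to reactive ankle moments and
    muscle activity in perturbed standing and walking, with phase-dependent,
    constant and sensory-modulated gain variants, uncentered goodness-of-fit
    statistics, and paired/repeated-measures model comparisons. Ships a
    linearized inverted-pendulum simulator with delayed proportional-derivative
    feedback as a ground-truth generator, so every identification stage is
    verifiable by parameter recovery. Includes a canonical columnar trial
    format, importers, and a command-line interface for simulation, fitting,
    comparison and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
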