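Package: hifcycle
Title: Hypoxia-Mediated Cell Cycle Commitment Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Single-cell kinetic model of oxygen-dependent commitment to the
    cell cycle at the G1/S restriction point. Couples exponential
    oxygen-response curves for the hypoxia-inducible factors Hif1a and Hif2a,
    and a threshold-activated reactive-oxygen-species (ROS) protein
    deactivation term, to a 13-species Myc-Rb-E2F reaction network integrated
    as a stiff ODE system. Provides commitment-time detection by E2F threshold
    crossing, characterisation curves of commitment time versus oxygen tension
    with derived statistics (optimal oxygen, convexity factor k, quiescence
    boundary), derivative-based global sensitivity measures (DGSM) integrated
    over the parameter hypercube with Sobol quasi-Monte-Carlo sampling, and
    parameter-space simulation campaigns including deactivation-steepness and
    activation-threshold sweeps, mechanism knockouts and an initial-condition
    multistability scan.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
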