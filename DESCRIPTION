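Package: ventsim
Title: Simulation and Waveform Analysis for Diaphragm-Assist Ventilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An in-silico respiratory-mechanics surrogate for an
    anaesthetized porcine model of respiratory insufficiency, together
    with the waveform-analysis pipeline used to evaluate a pneumatic
    artificial muscle (PAM) diaphragm-assist system. Includes a
    single-compartment equation-of-motion simulator with a CO2
    chemoreflex drive, a McKibben actuator force model, flow-triggered
    and fixed-rate actuation controllers, breath segmentation and
    ventilation metrics from spirometry, actuation-timing alignment
    regressions, transdiaphragmatic pressure analysis, and
    Campbell-diagram work-of-breathing computation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
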