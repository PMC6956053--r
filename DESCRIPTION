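Package: ecmonitor
Title: Electrochemical and Image-Based Monitoring of Bacterial Colonization
    in Microelectrode Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated analysis of bacteria growing in confined, non-fluidic
    microsystems with embedded gold microelectrodes. Provides seeded synthetic
    generators for time-lapse microchannel image stacks, cyclic voltammetry
    (CV) sessions and electrochemical impedance spectroscopy (EIS) sessions;
    an image pipeline (channel border detection by Hough transform, geometric
    rectification, percentile texture segmentation, growth-phase extraction);
    normalized-variance single-changepoint detection of the colonization
    event with change ratios; CV redox peak identification and change-ratio
    analysis; constant-phase-element equivalent-circuit impedance models with
    complex nonlinear least-squares fitting; and rule-based classification of
    colonization, control and electrode-damage events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
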