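Package: embryoject
Title: Simulation and Analysis of Robot-Assisted Zebrafish Embryo Microinjection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale digital twin of a robot-assisted batch microinjection
    system for zebrafish embryos. Implements the optics and mechanics of a
    four-fiber Bragg-grating (FBG) micro-force sensor glued to the injection
    needle, least-squares calibration of the shift-to-force decoding matrices
    from pitch/roll load sweeps, closed-form micromechanics of a spherical
    embryo held at a microfluidic suction port (net weight, contact geometry,
    minimum drag, critical holding pressure with surface-tension correction),
    proportional-derivative transport and needle-positioning control with a
    two-speed puncture schedule, detection of membrane-rupture events from
    force-trace jumps, seeded synthetic data generators for calibration sweeps,
    puncture traces and perception noise, a per-cell injection state machine
    with batch execution, and batch performance metrics (injection efficiency,
    puncture success rate, survival rate) with comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
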