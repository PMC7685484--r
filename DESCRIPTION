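Package: thermocell
Title: Simulation and Analysis of Stage-Top Temperature Control for
    Single-Cell Microbial Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A software twin of a low-cost Peltier-based stage-top
    temperature controller for live-cell microscopy, together with the
    single-cell analysis chain used to quantify temperature-shift
    phenotypes in rod-shaped bacteria. Provides NTC thermistor
    beta-parameter calibration, a lumped first-order thermal plant under
    discrete PID/PWM feedback with programmable setpoint waveforms
    (holds, steps, staircases, oscillations), trace-level analytics
    (stability, equilibration time, heating/cooling time constants), a
    ground-truthed synthetic phase-contrast time-lapse generator whose
    cells grow, divide and express temperature-sensitive phenotypes
    (filamentation, rounding, shrinkage), and a quantification pipeline
    covering drift registration, segmentation, subpixel contour and
    centerline geometry, lineage tracking, growth-rate estimation and
    division statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    tiff,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
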