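Package: strikelab
Title: Strike Kinematics and Ground Reaction Forces of Snake Strikes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for synchronized force-plate and high-speed
    video recordings of snake defensive strikes. Reads 1 kHz six-axis force
    traces and 500 Hz digitized head/tail coordinates, rotates both into a
    strike-aligned frame, smooths signals with generalized cross-validated
    splines, detects the strike window, and computes strike metrics
    (peak forces in body weights, head velocity and acceleration, fore-aft
    impulse, strike distance, tail kinematics, the fore-aft to vertical
    force ratio and the fraction of the strike above the Coulomb slip
    threshold). Includes a two-mass Newtonian strike simulator with an
    open-substrate friction cap, a momentum-budget decomposition of the
    head's momentum change into ground impulse and tail counter-momentum,
    and the statistical layer used for setup comparisons (mixed-model
    ANOVA, Brown-Forsythe variance tests, Holm step-down correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    yaml,
    jsonlite,
    car,
    lme4,
    lmerTest
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
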