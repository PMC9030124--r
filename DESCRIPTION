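Package: exposcore
Title: Occupational Exposure Score Models, Calibration, and Validation Harness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Open re-implementations of the multiplicative occupational
    exposure-score model family (the Cherrie 1996/1999 scores, the
    STOFFENMANAGER score B, and the Advanced REACH Tool score Ct), together
    with the lognormal mixed-effects machinery used to calibrate
    dimensionless exposure scores against measured concentrations, a
    mechanistic two-compartment near-field/far-field mass-balance
    counterpart, a synthetic calibration-study generator with assessor
    assignment noise, and an evaluation harness encoding model-vs-measurement
    statistics, residual-trend detection, percentile exceedance, Dutch
    Social Economic Council acceptance criteria, and tiered-assessment
    conservatism checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
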