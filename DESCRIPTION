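Package: picmetrics
Title: Paired Motor Unit Estimates of Persistent Inward Currents from
    Ramp Contractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for motor-unit spike trains and torque traces
    recorded during triangular isometric ramp contractions. Computes
    paired-motor-unit delta F (the standard estimate of the persistent inward
    current contribution to motoneuron self-sustained firing), brace height
    and attenuation slope from support-vector-regression smoothed discharge
    rates, peak discharge rates, recruitment and derecruitment thresholds,
    and contraction impulse. Includes torque filtering and ramp quality
    control, a motoneuron-pool simulator with known recruitment-derecruitment
    hysteresis for validation, and linear mixed-effects before/after condition
    contrasts with estimated marginal means.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    emmeans,
    jsonlite,
    lme4,
    pracma,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
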