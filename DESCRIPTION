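Package: inrsteady
Title: Predicting Time to Steady-State INR and Steady-State INR from
    Paired Factor VII and INR Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for individualised warfarin monitoring based on the
    sensitivity of the International Normalised Ratio (INR) to clotting
    factor VII. From two timed, paired measurements of INR and factor VII
    taken after factor VII has equilibrated (day 3 and day 4 by default),
    the package estimates the rate of change of the sensitivity index,
    inverts a dose-dependent logistic model to obtain the reference dose
    that a typical patient would need for the same anticoagulant response,
    and computes closed-form predictions of the time to steady-state INR
    and the steady-state INR itself. Also provides the nonlinear
    least-squares calibration machinery that produced the empirical
    sub-models (proportional sensitivity-index approximation, logistic
    slope family, quadratic rate map) and a seeded synthetic-patient
    generator for end-to-end testing of the whole pipeline.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
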