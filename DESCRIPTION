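Package: oscillab
Title: Endoscopic Oscillometry for Monitoring Abdominal Compliance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating abdominal compliance during laparoscopic
    insufflation with endoscopic oscillometry (the forced oscillation
    technique applied through the insufflation circuit). Provides a
    lumped-parameter virtual abdomen for simulating pressure/flow
    recordings and static pressure-volume staircases, Welch cross-spectral
    impedance estimation with magnitude-squared coherence, RLC model
    inversion yielding dynamic compliance, an exponential pressure-volume
    model yielding static compliance, and the quadratic calibration
    relating the two.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
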