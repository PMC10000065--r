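Package: logisuff
Title: Measurement Sufficiency for Logistic Tumor Growth Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for asking how many serial tumor volume
    measurements are needed to identify the parameters of the logistic growth
    model (intrinsic growth rate and carrying capacity) under clinically
    realistic measurement noise. Provides geometric tumor volume
    reconstruction from caliper/imaging axes, nested cohort calibration with
    a uniform growth rate and patient-specific carrying capacities,
    interpolation of ground-truth curves at typical scan days, multiplicative
    uniform noise injection with protected endpoints, bounded multistart
    least-squares estimation, error metrics and Mann-Whitney U comparisons
    across measurement counts, and a synthetic two-timepoint breast cancer
    cohort generator so the whole study runs without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
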