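Package: lungvct
Title: Virtual Clinical Trials for Chemoradiation in Non-Small Cell Lung Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates virtual patient cohorts of non-small cell lung cancer
    under combined chemoradiation. Tumor burden follows Gompertz growth toward
    a carrying capacity, radiation cell kill follows the linear-quadratic
    model, and chemotherapy follows a log-cell-kill pharmacodynamic model with
    exponentially decaying drug concentration. Monte Carlo sampling of patient
    populations yields Kaplan-Meier survival curves, arm comparisons for
    sequential versus concurrent chemoradiation schedules, growth-rate
    stratification, and volume-doubling-time summaries. A staged fitting
    cascade estimates population growth, radiosensitivity and chemotherapy
    parameters from observed monthly survival curves, and a fixture generator
    produces synthetic reference curves for offline parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    deSolve,
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
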