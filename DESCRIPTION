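Package: ghsdid
Title: Doubly-Robust Difference-in-Differences for Health-Security Scores
    and Immunization Coverage Panels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies whether countries' health-security capacity, as
    measured by a hierarchical composite score such as the Global Health
    Security Index, safeguarded essential childhood immunization coverage
    during the COVID-19 pandemic years 2020-2022.  Assembles
    country-vaccine-year coverage panels from WUENIC-style tables,
    re-computes equal-weight composite scores after removing a component,
    estimates average treatment effects on the treated with a doubly-robust
    difference-in-differences estimator (inverse-probability-of-treatment
    weighting combined with outcome-regression adjustment, influence-function
    cluster inference), tests parallel pre-trends with event-study placebos,
    sweeps treatment cutoffs on a sliding scale to find the minimum
    qualifying threshold, and generates synthetic study panels for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
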