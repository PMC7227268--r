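Package: nestedcc
Title: Matched Nested Case-Control Analysis for Longitudinal Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for embedding a matched nested case-control analysis in a
    longitudinal cohort or randomised trial with daily exposure logs. Builds
    incidence-density risk sets at each case's event time, selects controls by
    exact matching on categorical factors and minimal Mahalanobis distance on
    continuous factors, classifies time-truncated exposures from daily feed
    logs with configurable gap filling, and estimates exposure odds ratios by
    conditional logistic regression with a Newton-Raphson fitter. A cohort
    simulator with known ground truth supports parameter-recovery and
    design-efficiency experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite
Config/testthat/edition: 3
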