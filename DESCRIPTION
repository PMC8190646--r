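Package: feverpghd
Title: Fever Analytics for Patient-Generated Temperature and Antipyretic Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing caregiver-entered fever diaries: validation and
    filtering of child-level temperature and antipyretic dosing records,
    threshold-crossing fever-episode segmentation with linear imputation on
    irregular series, construction of 72-hour treatment cases anchored at the
    first antipyretic administration, classification into single versus
    combination antipyretic regimens, and comparison of fever exposure via the
    baseline-anchored area under the temperature-change curve at 6-12 hour
    horizons with Student t tests, chi-square tests, Cohen effect sizes and
    mixture-total summaries. Includes a calibrated synthetic-cohort generator
    with analytic ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
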