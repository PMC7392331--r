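Package: bwspref
Title: Best-Worst Scaling Analysis of Sectoral Resource-Allocation Preferences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing best-worst scaling
    (MaxDiff) surveys of budget-allocation preferences. Generates
    frequency-balanced choice-task designs, simulates sequential best-then-worst
    choices under a conditional-logit process, computes count-based
    best-minus-worst scores with one- and two-sample t-tests, fits the
    sequential best-worst conditional logit by maximum likelihood with effects
    coding and omitted-level recovery, and converts scores into percentage
    preference shares for comparison against actual budget allocations. Ships
    the published per-sector tallies and national-budget shares from a Ugandan
    multisectoral priority-setting survey as packaged fixtures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
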