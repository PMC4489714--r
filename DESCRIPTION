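Package: fish1p19q
Title: Automated Scoring of 1p/19q Status from FISH Signal Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based scoring of chromosome 1p and 19q status from
    per-nucleus fluorescence in situ hybridization (FISH) green/red probe
    signal counts. Implements nucleus-level classification under an open
    ISPO-style analysis grid and a fixed 24-combination lookup, case-level
    arm-status calling by the combination, ratio and combination+ratio
    counting methods, control-based mean+3SD cutoff calibration, concordance
    statistics (percent agreement, Cohen's kappa, chi-square homogeneity),
    per-combination logistic-regression screening to derive rule sets from a
    labeled series, and a synthetic FISH-count simulator with nuclear
    truncation artifacts for validation experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
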