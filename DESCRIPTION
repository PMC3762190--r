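Package: capscore
Title: Severity Scoring and Diagnostic Accuracy for Community-Acquired
    Pneumonia Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the CURB-65 and CRB-65 community-acquired pneumonia
    severity criteria together with their age-independent shock-index
    counterparts (CURSI, CURASI, CRSI, CRASI), including the adjusted shock
    index that discounts heart rate for fever. Provides a deterministic
    bounds rule for records with missing score components, 2x2 severity-by-
    outcome tables, sensitivity/specificity/predictive values with
    continuity-corrected Wilson confidence intervals, paired comparison of
    criteria (exact Wilcoxon signed-rank and exact McNemar tests), a
    seedable synthetic cohort generator moment-matched to a published
    inpatient audit cohort, and tabular report rendering. All user-facing
    functions take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
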