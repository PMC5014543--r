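Package: trajsat
Title: Detecting Survey Satisficing from Longitudinal Response-Speed Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify survey satisficers in longitudinal cohorts from
    interview paradata. Computes per-visit response speed (responded words per
    second) from survey start/end timestamps, applies the standard exclusion
    filters for corrupted timestamp records, fits group-based trajectory models
    (finite mixtures of polynomial mean trajectories estimated by EM with BIC
    model selection), applies a two-step classification that flags groups and
    subgroups whose fitted speed accelerates over recent visits, and estimates
    covariate associations with satisficing via repeated-measures (GEE-type)
    logistic models with exchangeable working correlation and robust standard
    errors. Includes a synthetic longitudinal cohort generator with planted
    trajectory groups, covariate effects, missing visits and timestamp
    corruption, so the whole pipeline is testable without restricted cohort
    data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
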