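Package: ssafi
Title: Stimulus-Specific Adaptation and Familiarity-Index Analysis for
    Songbird Auditory Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies neuronal memory for conspecific songs from
    trial-wise multiunit response magnitudes recorded in the songbird
    auditory forebrain. Computes normalized stimulus-specific adaptation
    (SSA) rates by linear regression over the linear region of the
    adaptation profile, derives per-site Familiarity Index (FI = N/F)
    values from novel versus familiar song adaptation rates, pools FI into
    group/hemisphere/region medians, and runs the accompanying inferential
    battery (sign tests against unity, two-sample Kolmogorov-Smirnov
    tests, t tests, Bonferroni correction). Includes a delta-delta-CT
    relative gene-expression module for companion qPCR data, a synthetic
    cohort generator with known ground truth for validation and power
    analysis, and an end-to-end pipeline producing a machine-readable
    report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
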