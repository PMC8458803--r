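Package: natsc
Title: Quantitative Sodium (23Na) MRI Simulation, Relaxometry and Cohort Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantitative brain sodium (23Na) MRI at ultra-high field:
    a digital phantom simulator producing multi-echo magnitude volumes with known
    ground truth, voxelwise bi-exponential T2* relaxometry recovering the signal
    ordinate at echo time zero, phantom-tube calibration of fitted signal to
    absolute total sodium concentration (TSC, mmol/L wet tissue), region-of-interest
    extraction with intracranial-volume normalized volumes, and a nonparametric
    group-comparison battery (exact Wilcoxon rank-sum, Fisher exact, chi-square,
    Spearman correlation, Bonferroni control) for small patient-control cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    optparse,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
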