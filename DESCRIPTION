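Package: hemishift
Title: Longitudinal Brain Asymmetry Change Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying how structural brain asymmetry
    changes between two imaging visits. Computes lateralization indices from
    bilateral image-derived phenotypes, deconfounds and standardizes them,
    fits or projects orthonormal whole-brain asymmetry patterns, and derives
    lateralized (LBAC) and magnitude (MBAC) asymmetry-change rates anchored to
    relative hemispheric grey-matter decline. Downstream analyses cover
    Cohen's d group contrasts (sex, baseline-age quartiles, employment
    status), cross-pattern correlation structure, L2-penalized phenome-wide
    regressions with permuted-label nulls, prediction of total brain-volume
    change, and a medical-diagnosis-wide association scan built on
    ICD-to-phecode aggregation, permutation-calibrated per-class principal
    components, and CCA/PLS composite disease clusters with Bonferroni and
    FDR control. A synthetic-cohort generator with planted ground-truth
    effects supports end-to-end recovery testing.
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
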