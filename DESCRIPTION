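Package: dentage
Title: Dental Age Estimation from Root Apexification and Tooth-Maturity Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates dental age in children and adolescents from panoramic
    radiograph readings using two complementary approaches: a stepwise ladder of
    tooth groups ordered by eruption timing, where dental age is the value of the
    last group with fully closed root apices (with a root-fraction interpolation
    fallback for subjects below the first ladder rung), and a table-driven
    maturity-score method in which the seven left mandibular teeth are staged A-H,
    scored with sex-specific weights and converted to an age via a conversion
    curve. Includes the full method-comparison toolkit used in agreement studies
    (age-by-sex bias tables, Wilcoxon signed-rank tests with exact tie-aware
    enumeration, Pearson correlation, regression slope-equality tests, and all six
    Shrout-Fleiss intraclass correlation forms with confidence intervals), plus a
    cohort simulator with correlated per-tooth maturation timing, sex-specific
    advancement and rater misclassification noise, so every pipeline stage can be
    exercised without radiographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
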