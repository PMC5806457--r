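Package: leafagree
Title: Observer Agreement and Annotation-Effort Analysis for Leaf-Count
    Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how reliably humans (experts, non-experts and
    citizen-science volunteers) count leaves in top-view images of Arabidopsis
    rosettes, and how much annotation effort a longitudinal phenotyping study
    actually needs.  Provides a synthetic cohort and observer simulator
    (genotype-dependent leaf emergence, resolution-dependent young-leaf
    misses, citizen pools with confidence responses), an agreement-metric
    suite (difference in count, mean squared error, R-squared, Krippendorff's
    alpha on a ratio scale), multiplicity-coloured Bland-Altman grids for
    discrete counts, mixed-effect repeated-measures inference on the
    genotype-by-time interaction, a Monte-Carlo observer-subsampling study,
    and consensus aggregation of crowd-sourced counts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
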