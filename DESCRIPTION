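Package: transdx
Title: Transdiagnostic Symptom Subtyping with Stability, Discriminant and
    Mediation Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for data-driven subtyping of neurodevelopmental cohorts
    (autism spectrum disorder, attention-deficit/hyperactivity disorder and
    typically developing controls) from questionnaire subscale scores.
    Implements agglomerative hierarchical clustering of symptom z-scores with
    gap-statistic model selection, subsample/adjusted-Rand cluster stability,
    linear discriminant validation, one-way ANOVA and ANCOVA with partial eta
    squared and Bonferroni post-hoc tests, an ANOVA-from-summary-statistics
    bridge for published tables, Pearson correlation grids, and parallel
    mediation path models with bias-corrected bootstrap confidence intervals
    and maximum-likelihood fit indices (RMSEA, CFI). Includes a synthetic
    cohort generator emulating the group- and cluster-level structure of a
    combined ASD/ADHD sample with white-matter tract fractional anisotropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    MASS,
    car,
    jsonlite,
    withr
Config/testthat/edition: 3
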