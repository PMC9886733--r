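Package: frailtykit
Title: Data-Driven Frailty Index Construction and Evaluation
Version: 0.1.0
Authors@R:
    person("Frailty", "Kit Developers", email = "maintainer@frailtykit.org",
           role = c("aut", "cre"))
Description: Tools for building deficit-accumulation frailty indices (FI)
    from mixed-type cohort data and for refining the deficit selection with
    an unsupervised, data-driven supplement to the standard procedure:
    factor analysis of mixed data (FAMD) with k-nearest-neighbour
    imputation, hierarchical clustering on principal components with
    k-means consolidation, per-deficit regressions against cluster
    membership with Benjamini-Hochberg false discovery rate control, and
    deficit-accumulation scoring under the standard missingness rule.
    Includes a diagnostic evaluation battery (single-feature linear
    discriminant classification with repeated stratified cross-validation,
    undersampling, external pseudo-fold validation and paired comparisons)
    and a prognostic battery (Kaplan-Meier quartile curves with log-rank
    tests, Cox proportional hazards models with Schoenfeld diagnostics,
    IPCW time-dependent AUC(t), and Prentice-weighted average hazard
    ratios), plus a synthetic-cohort generator with known latent structure
    so the whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
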