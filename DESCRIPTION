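Package: epimrs
Title: EWAS, Methylation Risk Scores and Epigenetic Clocks for Small
    Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for case-control DNA-methylation studies of
    the kind run on small psychiatric cohorts: matrix-level preprocessing
    (beta/M-value transforms, low-variability and blacklist filters,
    residual-PCA surrogate variables), per-CpG epigenome-wide association
    with covariates and genomic-inflation diagnostics, p-value-threshold
    methylation risk scores with phenotype association, linear epigenetic
    clocks with the Horvath age transform plus age-acceleration and
    stepwise-regression analyses, exact small-cohort group-comparison
    statistics, and a synthetic methylation-cohort generator with planted
    ground truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
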