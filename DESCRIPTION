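Package: shapeMR
Title: Two-Sample Mendelian Randomization for Composite Body-Shape Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) of
    principal-component body-shape phenotypes against disease outcomes from
    GWAS summary statistics. Covers instrument preparation (allele
    harmonization with palindrome handling, greedy LD pruning, proxy
    substitution), inverse-variance weighted estimation under fixed and
    multiplicative random effects, the MR-Egger, weighted-median and
    MR-PRESSO sensitivity suite (Cochran's Q, Egger intercept, I2GX/NOME,
    global/outlier/distortion tests, leave-one-out), a synthetic
    summary-statistics generator with known ground truth, and a pipeline
    that produces forest-table and diagnostics reports for exposure-by-
    outcome analysis grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'summary_io.R'
    'harmonization.R'
    'estimators.R'
    'presso.R'
    'simulate.R'
    'anthropometrics.R'
    'pipeline.R'
    'shapeMR-package.R'
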