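Package: wgrs
Title: Weighted Genetic Risk Scores and Recurrence Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes weighted genetic risk scores (wGRS) from SNP
    genotypes with rescaling for missing genotypes, categorizes scores on
    mean and standard-deviation thresholds, performs multiple imputation
    by chained equations with Rubin's-rules pooling, fits binary and
    multinomial logistic regressions for case-only association analyses
    of clinical diathesis features and post-surgical recurrence, and
    combines per-cohort estimates by fixed-effect inverse-variance
    meta-analysis.  Includes a synthetic cohort generator emulating a
    two-cohort surgical case-control study of Dupuytren's disease so the
    full pipeline can be exercised without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite,
    car,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    nortest,
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
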