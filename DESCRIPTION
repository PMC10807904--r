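Package: dcnet
Title: Covariate-Adjusted Differential Co-Abundance Network Analysis via
    Pseudo-Value Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies differentially connected taxa between two groups of
    microbiome samples while adjusting for covariates. Group-specific
    co-abundance networks are estimated with the SparCC compositional
    correlation procedure, per-taxon network connectivity is converted into
    jackknife pseudo-values by leave-one-out re-estimation, and the
    pseudo-values are regressed on the group indicator plus covariates with
    a least trimmed squares (LTS) robust estimator. Per-taxon p-values for
    every model term are converted to q-values for false discovery rate
    control. A paired two-timepoint mode tests for differential change of
    connectivity via differences of association matrices. Includes a
    synthetic logistic-normal-multinomial data generator with planted
    differential-connectivity structure for validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
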