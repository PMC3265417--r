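Package: methbatch
Title: Normalization and Empirical Bayes Batch Correction for Infinium
    Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for removing technical batch effects from Illumina
    Infinium-style DNA methylation array data. Implements three quantile
    normalization strategies for beta values and probe signals (direct
    quantile normalization of beta, color-channel adjustment followed by
    pooled-signal quantile normalization, and separate quantile
    normalization of methylated and unmethylated signals), followed by
    covariate-aware empirical Bayes location/scale batch adjustment.
    Includes quantitative batch-effect diagnostics (per-CpG ANOVA,
    principal component association tests, hierarchical clustering
    concordance, M-A curves, technical-replicate error metrics), readers
    and writers for GenomeStudio-style final reports, and a synthetic
    data generator emulating 27k-style two-signal arrays with
    controllable batch and outcome effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    sva,
    optparse
Config/testthat/edition: 3
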