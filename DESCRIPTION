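Package: longsig
Title: Bayesian Genetic Risk Models and Genetic Signatures of Exceptional Longevity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Case-control analysis toolkit for genome-wide studies of
    exceptional longevity. Implements closed-form Dirichlet-multinomial
    Bayes-factor association tests over four genetic models (genotypic,
    allelic, dominant, recessive) with maximum-Bayes-factor ranking and
    type-I-error calibration by simulation; quality control of samples and
    SNPs; principal-component ancestry clustering with ratio-preserving
    control matching; ensembles of nested naive-Bayes genetic risk models
    with per-subject risk profiles; and Bayesian model-based clustering of
    risk profiles into genetic signatures correlated with survival. A
    synthetic-data generator emulates the statistical structure of a
    centenarian case-control study so that every stage of the pipeline can
    be exercised and tested without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    mclust,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
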