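Package: twinace
Title: Classical Twin-Study ACE Variance Decomposition for Volumetric Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the classical twin design applied to continuous
    phenotypes such as brain structure volumes: simulation of monozygotic and
    dizygotic twin cohorts under an additive-genetic / shared-environment /
    unique-environment generative model, age- and sex-adjustment by
    residualization, intra-pair Pearson correlations with Fisher-z intervals,
    maximum-likelihood ACE/AE/CE/E/ADE variance decomposition on structured
    bivariate-normal pair likelihoods with profile-likelihood confidence
    intervals and likelihood-ratio model reduction, descriptive group
    comparisons, and cross-method agreement analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
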