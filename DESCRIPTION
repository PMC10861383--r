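Package: metabotypeR
Title: Metabotype Discovery and Differential Dietary Response Screening
    for Crossover Provocation Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to screen for differential symptom response
    (metabotypes) in three-arm crossover dietary provocation trials.
    Implements IBS-SSS response representations against the preceding
    washout week, a clustering grid over condensed response frames with
    minimum-size filtering and balanced downsampling, repeated double
    cross-validated random-forest screens (regression Q2 and
    classification rate) with recursive variable elimination and
    permutation calibration, PARAFAC trilinear decomposition of a
    postprandial metabolomics tensor with matrix-completion imputation
    and ANOVA linkage of component-score clusters to symptoms, ICC(2,1)
    feature-stability screening, and a synthetic-trial generator with
    plantable metabotypes and a global-null mode for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ranger,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'sim-config.R'
    'synth-trial.R'
    'synth-tensor.R'
    'io.R'
    'response.R'
    'clustering.R'
    'rdcv.R'
    'screens.R'
    'provocation.R'
    'parafac-impute.R'
    'parafac-als.R'
    'parafac-linkage.R'
    'assoc-stats.R'
    'metabotypeR-package.R'
    'pipeline.R'
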