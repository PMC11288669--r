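Package: eigenchoice
Title: Co-Expression Modules and Population-by-Trait Models for Brain Transcriptomes
Version: 0.1.0
Authors@R:
    person("Eigenchoice", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline linking bulk brain gene expression to
    population, social treatment, and display-trait variation in sympatric
    fish ecotypes. Provides a negative-binomial count simulator with planted
    co-expression modules and population-dependent trait slopes, count
    normalization and variance stabilization, sample PCA and quality-control
    flagging, signed weighted co-expression networks built from the biweight
    midcorrelation and topological overlap, dynamic branch cutting with
    eigengene merging, module-eigengene and candidate-gene linear models with
    type-II sums-of-squares ANOVA, a permutation-based empirical false
    discovery rate, a simplified negative-binomial differential-expression
    test, and a seeded end-to-end pipeline driver with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
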