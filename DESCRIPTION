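Package: hybripred
Title: Metabolic Prediction of Maize Hybrid Field Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step classification-driven framework for predicting maize
    hybrid field performance from metabolic profiles of the parental inbred
    lines. Step one encodes the metabolic inheritance pattern (additivity,
    dominance, overdominance) of every analyte in every hybrid of a partial
    factorial Dent x Flint design using empirical-Bayes moderated t-contrasts,
    and ranks the parental analytes by their importance in multi-class
    classifiers of those patterns. Step two uses ranked parental-analyte
    subsets in support-vector models to predict quantitative (biomass) and
    qualitative (good/bad performer) hybrid performance, with permutation
    nulls, precision-recall analysis and threshold sweeps. A synthetic
    partial-factorial panel generator with planted inheritance classes and
    planted biomass determinants makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    ranger,
    glmnet,
    mixOmics,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    readxl,
    optparse
Config/testthat/edition: 3
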