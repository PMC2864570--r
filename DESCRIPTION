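Package: chemofit
Title: Chemogenomic Fitness Profiling: Co-Fitness, Conditional
    Essentiality and Drug-Target Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of genome-wide yeast chemogenomic fitness data
    from pooled deletion-strain screens. Provides gene-gene co-fitness
    and compound-compound co-inhibition networks with a mean+3SD
    significance threshold, inverse-document-frequency weighting and
    Tanimoto similarity of PubChem-style substructure fingerprints, ATC
    level-3 co-therapeutic calls, a size-preserving permutation test for
    conditionally essential protein complexes, and a 20-feature
    random-forest predictor of drug-target interactions with a decision
    stump baseline, ten-fold cross-validation and precision-coverage
    evaluation. Includes a synthetic-data generator with planted targets,
    co-fit modules and compound families for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    randomForest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
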