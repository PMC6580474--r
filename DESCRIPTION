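Package: forkscan
Title: Integrated Transcriptome-Metabolome Prioritization and Metabolic
    Fork Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-tiered statistical-learning workflow for joint
    transcriptome and metabolome cohorts: tissue-enrichment z-score
    subsetting of genes against a multi-tissue expression compendium,
    k-means partitioning of z-score standardized biomolecules, per-cluster
    random-forest ranking by mean decrease in Gini impurity, hierarchical
    clustering of the prioritized biomolecules, and detection of "metabolic
    forks" - metabolite triplets (A, B, C) whose A versus B/C regression
    slope differs between control and treatment conditions, tested through
    the interaction term of a linear model. Includes a synthetic-data
    generator that plants enriched genes, feature profile groups,
    condition-discriminative features and forks, with a machine-readable
    ground-truth record for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
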