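Package: goldilocks
Title: Model Selection for Ligand-Based Bioactivity Modeling from Dataset
    Size and Scaffold Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for deciding which model family to use on a
    single-target bioactivity dataset. Implements curation of
    SMILES/activity tables (unit conversion to -log[M], InChIKey
    deduplication, activity binarization, stratified splitting), a
    scaffold-diversity score derived from the area under the cumulative
    scaffold frequency plot (div = 2(1-AUC) over Bemis-Murcko
    scaffolds), an episodic few-shot prototypical classifier over
    circular fingerprints with attention-based embedding refinement,
    classical fingerprint baselines (SVC/SVR, random forest, kNN,
    logistic) under nested cross-validation, a greedy tree-sums
    meta-classifier that learns which model family wins from (size,
    diversity) alone, and a synthetic-data generator producing
    chemically valid datasets with exactly controlled scaffold
    diversity and planted activity rules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    class,
    e1071,
    graphics,
    grDevices,
    jsonlite,
    methods,
    randomForest,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
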