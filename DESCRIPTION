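Package: predr
Title: Drug Repositioning by Kernel Fusion of Structure, Target and Side-Effect Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts novel drug-disease associations by integrating heterogeneous
    drug similarity measures. Drugs are profiled by chemical substructure
    fingerprints, target-protein sequences and side-effect annotations; diseases
    by a phenotype similarity matrix. Drug-drug similarities (weighted cosine
    over binary profiles, normalized Smith-Waterman over target sets) are fused
    and paired with disease similarity through a Kronecker product kernel, and a
    support vector machine trained on gold-standard associations with balanced
    negative sampling scores candidate pairs. Includes the associated evaluation
    protocols (stratified 10-fold and leave-one-drug-out cross-validation, ROC
    and precision-recall analysis, trivial-prediction filtering), descriptive
    network and correlation analyses, and a synthetic benchmark generator with
    planted class structure for offline testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
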