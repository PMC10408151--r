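Package: cptransfer
Title: Cross-Protein Transfer Models for Missense Variant Effect Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains cross-protein transfer (CPT) models that predict the
    pathogenicity of missense variants in proteins never seen during
    training. Features are derived from shallow vertebrate/mammal
    multiple sequence alignments (wild-type, mutant and gap frequencies),
    predicted structures (sidechain contact counts, per-residue
    confidence, and structure-conditioned residue frequencies from a deep
    alignment), external protein-model scores consumed as log-probability
    columns, and amino-acid descriptor differences. Missing features are
    completed by weighted K-nearest-neighbour imputation within or across
    genes. Per-protein linear or logistic models are fit on deep
    mutational scanning data, ensembled by prediction averaging, and
    assessed by leave-one-protein-out cross-validation with clinical-style
    metrics (AUROC, specificity at fixed sensitivity, Spearman rank
    correlation). A seeded synthetic-family generator produces complete,
    internally consistent fixture data for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    bio3d,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
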