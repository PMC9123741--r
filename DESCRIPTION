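Package: xtclass
Title: Classification of Xylose-Transporting Sugar Transporters from Protein Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A sequence-based machine-learning pipeline for predicting whether a
    sugar transporter protein can transport D-xylose. Provides FASTA/label/region
    ingestion, greedy identity-based redundancy removal with protected positives,
    alignment-free descriptors (compositions, AAindex autocorrelation, amphiphilic
    pseudo-amino-acid composition, property-scale auto-cross covariance), profile
    features (PROSITE signature matching, position-specific scoring matrices, and a
    profile hidden Markov model built from the non-cytoplasmic domains of known
    xylose transporters, scored by the forward algorithm), class-imbalance
    resampling (SMOTE, edited nearest neighbours, and their combination),
    recursive feature elimination with cross-validation around a gradient-boosted
    tree learner, precision-oriented decision-threshold recalibration, and a
    reproducible end-to-end run with a synthetic benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    seqinr,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
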