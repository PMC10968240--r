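Package: mkscreen
Title: Virtual Screening for Megakaryocyte-Differentiation Inducers with
    Hybrid Fingerprint Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ligand-based virtual screening of compound libraries for
    inducers of megakaryocyte differentiation and platelet production.
    Implements the full pipeline: SMILES ingestion and canonicalization,
    minority-class augmentation by randomized SMILES enumeration,
    Tanimoto-similarity diagnostics and MaxMin diversity selection for
    class balancing, dual molecular-fingerprint featurization (MACCS-167
    and Morgan/circular-2048), a hybrid convolutional-plus-dense neural
    network classifier trained with Adam on binary cross-entropy, the
    associated confusion-matrix and ranking metrics (accuracy, precision,
    recall, F-value, MCC, AUROC, AUPRC), and threshold-based ranked
    screening of unlabeled libraries. A seeded synthetic-library
    generator with a planted substructure rule supports end-to-end
    benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
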