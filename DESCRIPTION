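Package: luxpred
Title: Bioluminescent Protein Prediction from Physicochemical Sequence
    Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a protein is bioluminescent from its primary
    sequence alone. Each sequence is encoded as the per-residue mean of
    AAindex physicochemical property scales, the resulting feature matrix
    is reduced with filter feature selection (ReliefF, information gain
    with MDL discretization, or minimum-redundancy maximum-relevance),
    and a Gaussian-kernel support vector machine tuned by stratified
    cross-validated grid search performs the binary classification.
    Includes readers for FASTA and AAindex1 flat files, evaluation by
    accuracy, sensitivity, specificity, Matthews correlation coefficient
    and ROC/AUC, and a synthetic-data generator so the whole pipeline can
    be exercised and calibrated without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
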