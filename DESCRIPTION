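Package: mptype
Title: Membrane Protein Type Prediction from Functional Domain Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multilabel prediction of membrane protein types from functional
    domain annotations. Domain terms are treated as words and each protein's
    annotation set as a sentence; word2vec-style embeddings (CBOW or skip-gram
    with negative sampling, implemented natively) turn terms into vectors and
    proteins into averaged feature vectors, with a one-hot encoding as
    baseline. Classification uses a native RAKEL (random k-labelsets)
    label-powerset ensemble or Binary Relevance over pluggable base
    classifiers (random forest, SVM). Includes the exact-match, Jaccard
    accuracy, hamming-loss and integrated-score evaluation measurements,
    tenfold cross-validation with repeated runs and grid search, a synthetic
    annotation-data generator for end-to-end validation, and a command-line
    pipeline front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    randomForest,
    e1071,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
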