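Package: imbga
Title: Hybrid Resampling, F-Score Feature Selection and GA-Optimized
    Stacked Ensembles for Imbalanced Clinical Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for binary classification of heavily imbalanced tabular
    medical data. Implements AMOM-DUMS hybrid resampling (nearest-neighbour
    interpolation oversampling of the minority class followed by iterative
    Tomek-link boundary cleaning), standard and improved F-score filter
    feature selection with a cross-validated wrapper over subset sizes, and
    a two-layer stacked ensemble whose first-layer classifier subset is
    chosen by a genetic algorithm with AUC fitness (roulette selection,
    multi-point crossover and mutation, elitism). Includes a synthetic
    generator for imbalanced Gaussian-mixture datasets with informative,
    redundant and noise features, evaluation metrics (ROC/AUC, recall,
    F-score), an end-to-end pipeline and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    class,
    e1071,
    glmnet,
    jsonlite,
    kernlab,
    randomForest,
    rpart,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
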