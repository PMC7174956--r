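Package: stackDBP
Title: Stacked Ensemble Prediction of DNA-Binding Proteins from Profile
    HMM Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts DNA-binding proteins from evolutionary profiles.
    Parses HHsuite '.hhm' profile hidden Markov models, normalizes the
    match-state emission scores into probabilities, and encodes each
    protein as a 420-dimensional vector fusing amino acid composition
    (AAC, 20 features) with transition probability composition (TPC,
    400 features). Classification uses a two-stage stacked ensemble:
    configurable base classifiers (RBF-SVM, k-nearest neighbours,
    logistic regression, random forest, decision tree, extreme gradient
    boosting) emit out-of-fold class probabilities that feed a
    gradient-boosted decision tree meta-classifier. Includes jackknife
    (leave-one-out) and stratified k-fold cross-validation drivers,
    independent-test evaluation with accuracy, sensitivity, specificity,
    Matthews correlation coefficient and ROC/AUC, and a synthetic
    profile generator with controllable class separation for testing
    the full pipeline without external profile databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    class,
    e1071,
    glmnet,
    randomForest,
    rpart,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
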