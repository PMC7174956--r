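## Internal base-learner registry. Each learner is fit through the
## established implementation (e1071, class, glmnet, randomForest, rpart,
## xgboost) and exposes a single contract: fit on (X, y) and emit the
## positive-class probability on new rows. SVM/KNN/LR optionally
## standardize features with training-partition mean/variance; tree
## learners always consume raw features.

.defaultParams <- list(
  SVM_RBF = list(cost = 1, gamma = NULL),     # gamma NULL -> 1/ncol(X)
  KNN     = list(k = 5L),
  LR      = list(lambda = 0.01),              # ridge penalty
  RF      = list(ntree = 500L, mtry = NULL),  # mtry NULL -> sqrt(p)
  DT      = list(cp = 0.01, minsplit = 20L),
  XGB     = list(nrounds = 100L, max_depth = 3L, eta = 0.1)
)

# Default grid-search spaces; the benchmark method gives none, so these
# follow common practice for the learner family. Fully overridable.
defaultGrids <- function() {
  list(
    SVM_RBF = list(cost = c(0.1, 1, 10, 100),
                   gamma = 10^seq(-4, 0, length.out = 5)),
    KNN     = list(k = seq(1L, 31L, by = 2L)),
    LR      = list(lambda = c(0.01, 0.1, 1, 10)),
    RF      = list(ntree = c(100L, 300L, 500L)),
    DT      = list(cp = c(0.001, 0.01, 0.05)),
    XGB     = list(nrounds = c(100L, 300L, 500L), max_depth = c(3L, 6L))
  )
}

.needsStandardize <- function(name) name %in% c("SVM_RBF", "KNN", "LR")

.standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

.applyStandardizer <- function(std, X) {
  if (is.null(std)) return(X)
  sweep(sweep(X, 2L, std$center, "-"), 2L, std$scale, "/")
}

.fillParams <- function(name, params) {
  utils::modifyList(.defaultParams[[name]], params %||% list())
}

# Fit one base learner; returns an opaque fitted-learner record.
fitBaseLearner <- function(name, X, y, params = list(), standardize = TRUE, seed = 1L) {
  if (!name %in% LEARNER_NAMES) {
    stop("unknown base learner '", name, "'; valid: ",
         paste(LEARNER_NAMES, collapse = ", "))
  }
  assertBinaryLabels(y)
  if (length(unique(y)) < 2L) stop("base learner training requires both classes")
  p <- .fillParams(name, params)
  std <- if (standardize && .needsStandardize(name)) .standardizer(X) else NULL
  Xs <- .applyStandardizer(std, X)
  yf <- factor(y, levels = c(0L, 1L))
  fit <- withSeed(seed, switch(name,
    SVM_RBF = e1071::svm(x = Xs, y = yf, kernel = "radial",
                         cost = p$cost, gamma = p$gamma %||% (1 / ncol(Xs)),
                         probability = TRUE, scale = FALSE),
    KNN = list(X = Xs, y = yf, k = as.integer(p$k)),
    # glmnet warns about classes with < 8 members; that is routine in
    # leave-one-out stacking folds, so the warning is silenced here
    LR = suppressWarnings(
      glmnet::glmnet(Xs, yf, family = "binomial", alpha = 0,
                     lambda = p$lambda, standardize = FALSE)),
    RF = randomForest::randomForest(
           x = Xs, y = yf,
           ntree = as.integer(p$ntree),
           mtry = p$mtry %||% max(1L, floor(sqrt(ncol(Xs))))),
    DT = {
      df <- as.data.frame(Xs)
      names(df) <- paste0("V", seq_len(ncol(Xs)))
      df$.y <- yf
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = p$cp,
                                                  minsplit = as.integer(p$minsplit)))
    },
    XGB = xgboost::xgb.train(
            params = list(objective = "binary:logistic",
                          max_depth = as.integer(p$max_depth),
                          eta = p$eta, nthread = 1L),
            data = xgboost::xgb.DMatrix(Xs, label = y),
            nrounds = as.integer(p$nrounds), verbose = 0)
  ))
  list(name = name, params = p, std = std, fit = fit)
}

# Positive-class probability from a fitted-learner record.
predictBaseLearner <- function(learner, X) {
  Xs <- .applyStandardizer(learner$std, X)
  fit <- learner$fit
  switch(learner$name,
    SVM_RBF = {
      pr <- attr(stats::predict(fit, Xs, probability = TRUE), "probabilities")
      unname(pr[, "1"])
    },
    KNN = {
      k <- min(fit$k, nrow(fit$X))
      pred <- class::knn(train = fit$X, test = Xs, cl = fit$y, k = k, prob = TRUE)
      pwin <- attr(pred, "prob")
      ifelse(pred == "1", pwin, 1 - pwin)
    },
    LR = as.numeric(stats::predict(fit, Xs, type = "response")),
    RF = unname(stats::predict(fit, Xs, type = "prob")[, "1"]),
    DT = {
      df <- as.data.frame(Xs)
      names(df) <- paste0("V", seq_len(ncol(Xs)))
      unname(stats::predict(fit, df, type = "prob")[, "1"])
    },
    XGB = as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(Xs)))
  )
}

#' Grid-search hyperparameter tuning for one base learner
#'
#' Evaluates every point of a hyperparameter grid by stratified k-fold
#' cross-validated accuracy and returns the best parameter set; ties are
#' broken by first-in-grid order (the grid is expanded with the first
#' parameter varying fastest).
#'
#' @param name base learner name (`SVM_RBF`, `KNN`, `LR`, `RF`, `DT`, `XGB`).
#' @param fm a labeled [FeatureMatrix].
#' @param grid named list of parameter value vectors; defaults to the
#'   learner's entry in [defaultGrids()].
#' @param cvFolds number of stratified folds (>= 2).
#' @param seed integer seed driving fold assignment and stochastic fits.
#' @param standardize passed through to the learner pipeline.
#' @return list with `name`, `params` (the winning setting), `accuracy`
#'   (its mean CV accuracy), and `table` (accuracy per grid point).
#' @export
tuneBaseLearner <- function(name, fm, grid = NULL, cvFolds = 5L, seed = 1L,
                            standardize = TRUE) {
  stopifnot(is(fm, "FeatureMatrix"))
  y <- fm@labels
  if (!length(y)) stop("tuning requires a labeled feature matrix")
  if (length(unique(y)) < 2L) stop("tuning requires both classes")
  grid <- grid %||% defaultGrids()[[name]]
  if (is.null(grid) || !length(grid)) stop("empty hyperparameter grid")
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  folds <- stratifiedFolds(y, cvFolds, seed)
  acc <- numeric(nrow(pts))
  for (g in seq_len(nrow(pts))) {
    params <- as.list(pts[g, , drop = FALSE])
    correct <- 0L
    for (f in sort(unique(folds))) {
      tr <- folds != f
      lrn <- fitBaseLearner(name, fm@X[tr, , drop = FALSE], y[tr],
                            params = params, standardize = standardize,
                            seed = deriveSeed(seed, f, g))
      prob <- predictBaseLearner(lrn, fm@X[!tr, , drop = FALSE])
      correct <- correct + sum(as.integer(prob >= 0.5) == y[!tr])
    }
    acc[g] <- correct / length(y)
  }
  best <- which.max(acc)  # which.max returns the first maximum: tie rule
  list(name = name, params = as.list(pts[best, , drop = FALSE]),
       accuracy = acc[best],
       table = cbind(pts, cv_accuracy = acc))
}
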