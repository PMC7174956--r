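## Two-stage stacked ensemble: base classifiers produce out-of-fold
## positive-class probabilities (stage 1), a gradient-boosted decision
## tree meta-classifier consumes them (stage 2).

#' Construct a stacked-ensemble configuration
#'
#' The named combinations fix the base-learner sets:
#' SM1 = KNN, LR, DT, SVM_RBF; SM2 = KNN, LR, DT, XGB;
#' SM3 = KNN, LR, DT, RF; SM4 = SVM_RBF, XGB, RF;
#' SM5 = all six. Use `combination = "custom"` with an explicit
#' `baseLearners` vector for anything else. SM1 is the default final
#' predictor.
#'
#' @param combination `"SM1"`..`"SM5"` or `"custom"`.
#' @param baseLearners required for `"custom"`; ignored otherwise.
#' @param baseParams named list (by learner name) of hyperparameter
#'   overrides, e.g. `list(KNN = list(k = 7))`.
#' @param metaParams gradient-boosted tree meta hyperparameters
#'   (`nrounds = 100`, `max_depth = 3`, `eta = 0.1` by default).
#' @param nMetaFolds stratified folds for out-of-fold meta-features.
#' @param seed master seed for all randomized components.
#' @param standardize standardize features inside SVM/KNN/LR pipelines.
#' @return a [StackConfig].
#' @export
StackConfig <- function(combination = "SM1", baseLearners = NULL,
                        baseParams = list(), metaParams = list(),
                        nMetaFolds = 5L, seed = 1L, standardize = TRUE) {
  if (combination %in% names(SM_COMBINATIONS)) {
    baseLearners <- SM_COMBINATIONS[[combination]]
  } else if (combination == "custom") {
    if (is.null(baseLearners) || !length(baseLearners)) {
      stop("combination 'custom' requires a non-empty baseLearners vector")
    }
  } else {
    stop("unknown stacked-model combination '", combination, "'; valid names: ",
         paste(names(SM_COMBINATIONS), collapse = ", "), ", custom")
  }
  new("StackConfig", combination = combination,
      baseLearners = as.character(baseLearners),
      baseParams = baseParams,
      metaParams = utils::modifyList(list(nrounds = 100L, max_depth = 3L, eta = 0.1),
                                     metaParams),
      nMetaFolds = as.integer(nMetaFolds),
      seed = as.integer(seed),
      standardize = isTRUE(standardize))
}

#' Out-of-fold meta-features from the base learners
#'
#' Splits the training data into `nMetaFolds` stratified folds; for each
#' fold, every base learner is trained on the remaining folds and
#' predicts positive-class probabilities on the held-out fold. Row `r` of
#' the result is therefore produced by learners never trained on `r`'s
#' fold (the standard leakage-free stacking construction). One column per
#' base learner; the redundant negative-class probability is dropped.
#'
#' @param config a [StackConfig].
#' @param fm a labeled [FeatureMatrix]; each class must have at least
#'   `nMetaFolds` members.
#' @return n x B numeric matrix of probabilities, columns named by learner.
#' @export
generateMetaFeatures <- function(config, fm) {
  stopifnot(is(config, "StackConfig"), is(fm, "FeatureMatrix"))
  validObject(config)
  y <- fm@labels
  if (!length(y)) stop("meta-feature generation requires labels")
  if (length(unique(y)) < 2L) stop("both classes required")
  folds <- stratifiedFolds(y, config@nMetaFolds, config@seed)
  B <- length(config@baseLearners)
  M <- matrix(NA_real_, nrow = length(y), ncol = B,
              dimnames = list(NULL, config@baseLearners))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    for (b in seq_len(B)) {
      nm <- config@baseLearners[b]
      lrn <- fitBaseLearner(nm, fm@X[tr, , drop = FALSE], y[tr],
                            params = config@baseParams[[nm]],
                            standardize = config@standardize,
                            seed = deriveSeed(config@seed, f, b))
      M[!tr, b] <- predictBaseLearner(lrn, fm@X[!tr, , drop = FALSE])
    }
  }
  M
}

.fitMeta <- function(M, y, metaParams, seed) {
  withSeed(seed,
    xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = as.integer(metaParams$max_depth),
                    eta = metaParams$eta, nthread = 1L),
      data = xgboost::xgb.DMatrix(M, label = y),
      nrounds = as.integer(metaParams$nrounds), verbose = 0))
}

#' Train a two-stage stacked ensemble
#'
#' Stage 1: [generateMetaFeatures()] produces out-of-fold base-learner
#' probabilities. Stage 2: the gradient-boosted tree meta-classifier is
#' fit on those probabilities against the labels. Finally each base
#' learner is refit on the full training data for prediction time.
#' Constant meta-feature columns are permitted but flagged in the model
#' fingerprint (`degenerateMeta`).
#'
#' @param config a [StackConfig].
#' @param fm a labeled [FeatureMatrix] containing both classes.
#' @return a [StackedModel].
#' @export
trainStacked <- function(config, fm) {
  stopifnot(is(config, "StackConfig"), is(fm, "FeatureMatrix"))
  y <- fm@labels
  if (!length(y)) stop("training requires a labeled feature matrix")
  if (length(unique(y)) < 2L) stop("training requires both classes")
  M <- generateMetaFeatures(config, fm)
  meta <- .fitMeta(M, y, config@metaParams, deriveSeed(config@seed, 999L))
  base <- lapply(seq_along(config@baseLearners), function(b) {
    nm <- config@baseLearners[b]
    fitBaseLearner(nm, fm@X, y, params = config@baseParams[[nm]],
                   standardize = config@standardize,
                   seed = deriveSeed(config@seed, 0L, b))
  })
  names(base) <- config@baseLearners
  degenerate <- any(apply(M, 2L, function(col) max(col) - min(col) == 0))
  new("StackedModel",
      config = config,
      fittedBase = base,
      fittedMeta = meta,
      featureLayout = colnames(fm@X),
      fingerprint = list(n = length(y), nPos = sum(y == 1L), nNeg = sum(y == 0L),
                         seed = config@seed, ids = fm@ids,
                         degenerateMeta = degenerate))
}

.checkLayout <- function(model, fm) {
  if (ncol(fm@X) != length(model@featureLayout)) {
    stop("feature-count mismatch: model expects ", length(model@featureLayout),
         " features, input has ", ncol(fm@X))
  }
  if (!is.null(colnames(fm@X)) && !identical(colnames(fm@X), model@featureLayout)) {
    bad <- which(colnames(fm@X) != model@featureLayout)[1L]
    stop("feature-layout mismatch at column ", bad, ": model expects '",
         model@featureLayout[bad], "', input has '", colnames(fm@X)[bad], "'")
  }
}

#' Positive-class probabilities from a stacked model
#'
#' @param model a trained [StackedModel].
#' @param fm a [FeatureMatrix] whose 420 columns match the model's
#'   feature layout (labels, if any, are ignored).
#' @return numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predictProba <- function(model, fm) {
  stopifnot(is(model, "StackedModel"), is(fm, "FeatureMatrix"))
  .checkLayout(model, fm)
  M <- vapply(model@fittedBase, function(lrn) predictBaseLearner(lrn, fm@X),
              numeric(nrow(fm@X)))
  if (nrow(fm@X) == 1L) M <- matrix(M, nrow = 1L,
                                    dimnames = list(NULL, names(model@fittedBase)))
  p <- as.numeric(stats::predict(model@fittedMeta, xgboost::xgb.DMatrix(M)))
  pmin(pmax(p, 0), 1)
}

#' Class labels from a stacked model
#'
#' Label 1 (DNA-binding) is assigned when the positive-class probability
#' is greater than or equal to the threshold.
#'
#' @inheritParams predictProba
#' @param threshold decision threshold, strictly inside (0, 1).
#' @return integer vector of 0/1 labels.
#' @export
predictLabel <- function(model, fm, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)")
  }
  as.integer(predictProba(model, fm) >= threshold)
}

MODEL_FORMAT <- "stackDBP-model"
MODEL_FORMAT_VERSION <- 1L

#' Serialize a trained stacked model
#'
#' The artifact embeds the configuration, all fitted learners, the
#' feature layout, the training fingerprint and a format version.
#'
#' @param model a [StackedModel].
#' @param path output file path.
#' @return invisibly, the path written.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "StackedModel"))
  saveRDS(list(format = MODEL_FORMAT, version = MODEL_FORMAT_VERSION,
               model = model), path)
  invisible(path)
}

#' Load a stacked model saved by [saveModel()]
#'
#' @param path path to the serialized model.
#' @return a [StackedModel].
#' @export
loadModel <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file '", path,
                                           "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT)) {
    stop("file '", path, "' is not a stackDBP model artifact")
  }
  if (!identical(obj$version, MODEL_FORMAT_VERSION)) {
    stop("model format version ", obj$version, " not supported (expected ",
         MODEL_FORMAT_VERSION, ")")
  }
  obj$model
}
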