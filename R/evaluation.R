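## Confusion-matrix metrics, ROC/AUC, and the cross-validation drivers
## (jackknife = leave-one-out, stratified k-fold, independent test).

#' Confusion counts for binary predictions
#'
#' Positive class = DNA-binding = 1.
#'
#' @param yTrue,yPred equal-length 0/1 vectors.
#' @return named integer vector with TP, FP, TN, FN.
#' @export
confusionCounts <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("label vectors differ in length")
  assertBinaryLabels(yTrue, "true labels")
  assertBinaryLabels(yPred, "predicted labels")
  c(TP = sum(yTrue == 1L & yPred == 1L),
    FP = sum(yTrue == 0L & yPred == 1L),
    TN = sum(yTrue == 0L & yPred == 0L),
    FN = sum(yTrue == 1L & yPred == 0L))
}

.mcc <- function(cc, sqrtDenom = TRUE) {
  TP <- as.double(cc["TP"]); FP <- as.double(cc["FP"])
  TN <- as.double(cc["TN"]); FN <- as.double(cc["FN"])
  f <- c(TP + FP, TP + FN, TN + FP, TN + FN)
  if (any(f == 0)) return(0)
  den <- prod(f)
  num <- TP * TN - FP * FN
  if (sqrtDenom) num / sqrt(den) else num / den
}

#' Performance metrics from confusion counts
#'
#' Overall accuracy OA = (TP+TN)/n, sensitivity SN = TP/(TP+FN),
#' specificity SP = TN/(TN+FP), and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). MCC is 0
#' by definition when any denominator factor is 0; SN/SP with a zero
#' denominator are reported as `NA`, never silently 0. `mccLinear` is the
#' variant whose denominator is the plain product without the square
#' root, exposed for comparison; the square-root form is the standard
#' definition and the default `MCC`. AUC is computed from [rocCurve()]
#' when scores are supplied.
#'
#' @param counts output of [confusionCounts()].
#' @param yTrue,scores optional true labels and real-valued scores for
#'   ROC/AUC.
#' @return list with OA, SN, SP, MCC, mccLinear, AUC (NA without scores).
#' @export
computeMetrics <- function(counts, yTrue = NULL, scores = NULL) {
  n <- sum(counts)
  if (n < 1L) stop("metrics undefined for zero evaluated samples")
  TP <- as.double(counts["TP"]); FP <- as.double(counts["FP"])
  TN <- as.double(counts["TN"]); FN <- as.double(counts["FN"])
  sn <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(yTrue)) stop("AUC requires both yTrue and scores")
    auc <- rocCurve(yTrue, scores)$auc
  }
  list(OA = unname((TP + TN) / n), SN = unname(sn), SP = unname(sp),
       MCC = unname(.mcc(counts, TRUE)),
       mccLinear = unname(.mcc(counts, FALSE)),
       AUC = auc)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the distinct score values (tied
#' scores grouped), yielding a curve from (0,0) to (1,1); AUC is the
#' trapezoidal integral, which equals the Mann-Whitney U statistic
#' normalized by `nPos * nNeg` with ties counted 1/2.
#'
#' @param yTrue 0/1 labels, both classes present.
#' @param scores real-valued scores, larger = more positive.
#' @return list: `points` (data.frame FPR, TPR, threshold) and `auc`.
#' @export
rocCurve <- function(yTrue, scores) {
  assertBinaryLabels(yTrue, "true labels")
  if (length(yTrue) != length(scores)) stop("labels and scores differ in length")
  if (anyNA(scores)) stop("scores must not contain NA")
  nPos <- sum(yTrue == 1L); nNeg <- sum(yTrue == 0L)
  if (nPos == 0L || nNeg == 0L) stop("ROC requires both classes")
  thr <- sort(unique(scores), decreasing = TRUE)
  posAt <- vapply(split(yTrue, match(scores, thr)), function(v) sum(v == 1L), integer(1))
  negAt <- vapply(split(yTrue, match(scores, thr)), function(v) sum(v == 0L), integer(1))
  ord <- order(as.integer(names(posAt)))
  tpr <- c(0, cumsum(posAt[ord]) / nPos)
  fpr <- c(0, cumsum(negAt[ord]) / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(FPR = fpr, TPR = tpr,
                           threshold = c(Inf, thr)),
       auc = unname(auc))
}

.buildReport <- function(ids, yTrue, scores, protocol, threshold = 0.5) {
  yPred <- as.integer(scores >= threshold)
  cc <- confusionCounts(yTrue, yPred)
  roc <- rocCurve(yTrue, scores)
  metrics <- computeMetrics(cc, yTrue, scores)
  new("EvaluationReport",
      counts = cc,
      metrics = metrics,
      roc = roc$points,
      perSample = data.frame(id = ids, label = yTrue, score = scores,
                             predicted = yPred, stringsAsFactors = FALSE),
      protocol = protocol)
}

#' Stratified k-fold cross-validation of a stacked ensemble
#'
#' For each stratified fold a full stacked model is trained on the
#' remaining folds (meta-feature folds re-drawn from the config seed) and
#' scores the held-out proteins. Metrics are computed once over the
#' pooled out-of-fold predictions, and the ROC/AUC from the pooled
#' scores (a single curve, not an average of per-fold curves).
#'
#' @param config a [StackConfig].
#' @param fm a labeled [FeatureMatrix].
#' @param k number of folds; `k = n` reduces exactly to the jackknife.
#' @param seed fold-assignment seed (default: the config seed).
#' @param threshold decision threshold for the confusion counts.
#' @return an [EvaluationReport].
#' @export
kfoldEvaluate <- function(config, fm, k, seed = config@seed, threshold = 0.5) {
  stopifnot(is(config, "StackConfig"), is(fm, "FeatureMatrix"))
  y <- fm@labels
  if (!length(y)) stop("evaluation requires labels")
  n <- length(y)
  folds <- stratifiedFolds(y, k, seed)
  scores <- rep(NA_real_, n)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    model <- tryCatch(trainStacked(config, fm[which(tr)]),
      error = function(e) {
        stop("training failed with fold ", f, " held out (ids: ",
             paste(utils::head(fm@ids[!tr], 3L), collapse = ", "), "...): ",
             conditionMessage(e))
      })
    scores[!tr] <- predictProba(model, fm[which(!tr)])
  }
  .buildReport(fm@ids, y, scores,
               if (k == n) "jackknife" else sprintf("kfold(k=%d, seed=%d)", k, seed),
               threshold)
}

#' Jackknife (leave-one-out) evaluation of a stacked ensemble
#'
#' Every protein is scored by a full stacked model trained on all the
#' remaining proteins; metrics and the ROC are computed once over the
#' pooled n held-out predictions. This is the k = n special case of
#' [kfoldEvaluate()] and is O(n) full re-trainings.
#'
#' @inheritParams kfoldEvaluate
#' @return an [EvaluationReport] with protocol `"jackknife"`.
#' @export
jackknifeEvaluate <- function(config, fm, threshold = 0.5) {
  stopifnot(is(fm, "FeatureMatrix"))
  y <- fm@labels
  if (length(y) < 3L) stop("jackknife requires n >= 3")
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L) {
    stop("jackknife requires at least 2 members per class, otherwise some ",
         "training folds lose a class entirely")
  }
  kfoldEvaluate(config, fm, k = length(y), threshold = threshold)
}

#' Independent-test evaluation of a trained model
#'
#' Single prediction pass over a held-out labeled dataset. When the test
#' ids overlap the model's training fingerprint, a warning names the
#' overlap (the test is then not independent).
#'
#' @param model a trained [StackedModel].
#' @param fm a labeled [FeatureMatrix].
#' @param threshold decision threshold.
#' @return an [EvaluationReport] with protocol `"independent"`.
#' @export
independentTest <- function(model, fm, threshold = 0.5) {
  stopifnot(is(model, "StackedModel"), is(fm, "FeatureMatrix"))
  if (!nrow(fm@X)) stop("independent test requires a non-empty dataset")
  if (!length(fm@labels)) stop("independent test requires labels")
  overlap <- intersect(fm@ids, model@fingerprint$ids)
  if (length(overlap)) {
    warning("test set shares ", length(overlap),
            " id(s) with the training data (e.g. ",
            paste(utils::head(overlap, 3L), collapse = ", "),
            "); the evaluation is not independent")
  }
  scores <- predictProba(model, fm)
  .buildReport(fm@ids, fm@labels, scores, "independent", threshold)
}

#' Write an evaluation report as JSON (and per-sample scores as TSV)
#'
#' Percentages are reported to 2 decimals and MCC/AUC to 4 decimals in
#' the JSON summary; the raw unrounded values are kept in the object.
#'
#' @param report an [EvaluationReport].
#' @param jsonPath optional JSON output path.
#' @param tsvPath optional per-sample TSV output path.
#' @return invisibly, the report.
#' @export
writeReport <- function(report, jsonPath = NULL, tsvPath = NULL) {
  stopifnot(is(report, "EvaluationReport"))
  m <- report@metrics
  if (!is.null(jsonPath)) {
    payload <- list(
      protocol = report@protocol,
      counts = as.list(report@counts),
      metrics = list(
        OA_percent = round(100 * m$OA, 2),
        SN_percent = if (is.na(m$SN)) NA else round(100 * m$SN, 2),
        SP_percent = if (is.na(m$SP)) NA else round(100 * m$SP, 2),
        MCC = round(m$MCC, 4),
        MCC_linear = round(m$mccLinear, 4),
        AUC = if (is.na(m$AUC)) NA else round(m$AUC, 4)),
      roc = report@roc[, c("FPR", "TPR")],
      per_sample = report@perSample)
    jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", na = "null")
  }
  if (!is.null(tsvPath)) {
    utils::write.table(report@perSample, tsvPath, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}

#' Plot the ROC curve of an evaluation report
#'
#' @param report an [EvaluationReport].
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plotROC <- function(report) {
  stopifnot(is(report, "EvaluationReport"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotROC requires the ggplot2 package")
  }
  df <- report@roc
  ggplot2::ggplot(df, ggplot2::aes(x = FPR, y = TPR)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC [%s], AUC = %.4f",
                                  report@protocol, report@metrics$AUC)) +
    ggplot2::theme_minimal()
}
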