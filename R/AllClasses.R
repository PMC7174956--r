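#' @import methods
NULL

#' Raw profile HMM match emissions
#'
#' An `HMMProfile` holds the match-state emission block of an HHsuite
#' `.hhm` profile: an L x 20 matrix of integer scores in HHM units
#' (approximately \eqn{-1000 \log_2 p}), where `NA` encodes the `*`
#' marker HHsuite writes for negligible emission probabilities.
#'
#' @slot proteinId single protein identifier.
#' @slot residues one-letter residue string of length L (diagnostic only;
#'   never used in feature computation).
#' @slot rawScores L x 20 integer matrix; `NA` is the `*` (STAR) marker,
#'   all other entries are non-negative integers.
#' @slot alphabet the 20 amino-acid one-letter codes in the column order
#'   declared by the file header (HHsuite order by default).
#' @export
setClass("HMMProfile",
  representation(proteinId = "character",
                 residues  = "character",
                 rawScores = "matrix",
                 alphabet  = "character"))

setValidity("HMMProfile", function(object) {
  msg <- character()
  if (length(object@proteinId) != 1L) msg <- c(msg, "proteinId must be length 1")
  m <- object@rawScores
  if (ncol(m) != 20L) msg <- c(msg, "rawScores must have exactly 20 columns")
  if (nrow(m) < 1L) msg <- c(msg, "rawScores must have at least one row")
  if (!is.integer(m)) msg <- c(msg, "rawScores must be an integer matrix (NA = STAR)")
  v <- m[!is.na(m)]
  if (length(v) && any(v < 0L)) msg <- c(msg, "rawScores entries must be STAR (NA) or >= 0")
  if (length(object@alphabet) != 20L ||
      !setequal(object@alphabet, HH_ALPHABET) ||
      anyDuplicated(object@alphabet)) {
    msg <- c(msg, "alphabet must be a permutation of the 20 standard amino acids")
  }
  if (length(object@residues) != 1L || nchar(object@residues) != nrow(m)) {
    msg <- c(msg, "residues must be a single string of length L")
  }
  if (length(msg)) msg else TRUE
})

#' Normalized profile
#'
#' The emission matrix of an [HMMProfile] mapped into probabilities:
#' a score `x` becomes `2^(-x/1000)` and the STAR marker becomes exactly 0,
#' so every entry lies in `[0, 1]`.
#'
#' @slot proteinId,residues,alphabet as in [HMMProfile].
#' @slot mat L x 20 numeric matrix with entries in `[0, 1]`.
#' @export
setClass("NormalizedProfile",
  representation(proteinId = "character",
                 residues  = "character",
                 mat       = "matrix",
                 alphabet  = "character"))

setValidity("NormalizedProfile", function(object) {
  msg <- character()
  m <- object@mat
  if (ncol(m) != 20L) msg <- c(msg, "matrix must have exactly 20 columns")
  if (!is.numeric(m) || anyNA(m)) msg <- c(msg, "matrix must be numeric with no NA")
  else if (any(m < 0) || any(m > 1)) msg <- c(msg, "all entries must lie in [0, 1]")
  if (length(object@alphabet) != 20L || !setequal(object@alphabet, HH_ALPHABET)) {
    msg <- c(msg, "alphabet must be a permutation of the 20 standard amino acids")
  }
  if (length(msg)) msg else TRUE
})

#' Labeled two-class profile dataset
#'
#' @slot proteinIds unique protein identifiers.
#' @slot profiles list of [NormalizedProfile] objects, parallel to `proteinIds`.
#' @slot labels integer 0/1 vector; 1 = DNA-binding protein (positive class).
#' @export
setClass("LabeledDataset",
  representation(proteinIds = "character",
                 profiles   = "list",
                 labels     = "integer"))

setValidity("LabeledDataset", function(object) {
  msg <- character()
  n <- length(object@proteinIds)
  if (anyDuplicated(object@proteinIds)) msg <- c(msg, "protein ids must be unique")
  if (length(object@profiles) != n) msg <- c(msg, "profiles and ids must be parallel")
  if (length(object@labels) != n) msg <- c(msg, "labels and ids must be parallel")
  if (n && (anyNA(object@labels) || !all(object@labels %in% c(0L, 1L)))) {
    msg <- c(msg, "labels must be 0/1")
  }
  if (length(msg)) msg else TRUE
})

#' Feature matrix for the 420-dimensional profile encoding
#'
#' Rows are proteins; the 420 columns are the 20 AAC features followed by
#' the 400 row-major TPC features, named `AAC_<aa>` and `TPC_<aa_i>_<aa_j>`.
#'
#' @slot ids protein identifiers, one per row.
#' @slot X n x 420 numeric matrix with feature column names.
#' @slot labels integer 0/1 vector of length n, or `integer(0)` when the
#'   matrix is unlabeled (prediction-time input).
#' @export
setClass("FeatureMatrix",
  representation(ids = "character", X = "matrix", labels = "integer"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (nrow(object@X) != length(object@ids)) msg <- c(msg, "row count must equal number of ids")
  if (ncol(object@X) != 420L) msg <- c(msg, "feature matrix must have exactly 420 columns")
  if (any(!is.finite(object@X))) msg <- c(msg, "all feature values must be finite")
  if (length(object@labels) && length(object@labels) != length(object@ids)) {
    msg <- c(msg, "labels, when present, must be parallel to ids")
  }
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L))) {
    msg <- c(msg, "labels must be 0/1")
  }
  if (length(msg)) msg else TRUE
})

#' Stacked-ensemble configuration
#'
#' @slot combination one of `"SM1"`..`"SM5"` or `"custom"`.
#' @slot baseLearners character vector of base-learner names, each one of
#'   `SVM_RBF`, `KNN`, `LR`, `RF`, `DT`, `XGB`.
#' @slot baseParams named list (by learner name) of hyperparameter lists.
#' @slot metaParams hyperparameters for the gradient-boosted tree
#'   meta-classifier (`nrounds`, `max_depth`, `eta`).
#' @slot nMetaFolds stratified folds used to produce out-of-fold
#'   meta-features (default 5).
#' @slot seed integer master seed driving every randomized component.
#' @slot standardize whether SVM/KNN/LR pipelines standardize features
#'   using training-partition mean/variance (tree learners always consume
#'   raw features).
#' @export
setClass("StackConfig",
  representation(combination = "character",
                 baseLearners = "character",
                 baseParams = "list",
                 metaParams = "list",
                 nMetaFolds = "integer",
                 seed = "integer",
                 standardize = "logical"))

LEARNER_NAMES <- c("SVM_RBF", "KNN", "LR", "RF", "DT", "XGB")
SM_COMBINATIONS <- list(
  SM1 = c("KNN", "LR", "DT", "SVM_RBF"),
  SM2 = c("KNN", "LR", "DT", "XGB"),
  SM3 = c("KNN", "LR", "DT", "RF"),
  SM4 = c("SVM_RBF", "XGB", "RF"),
  SM5 = c("KNN", "LR", "DT", "SVM_RBF", "RF", "XGB"))

setValidity("StackConfig", function(object) {
  msg <- character()
  if (!object@combination %in% c(names(SM_COMBINATIONS), "custom")) {
    msg <- c(msg, paste0("unknown combination '", object@combination,
                         "'; valid names: ", paste(names(SM_COMBINATIONS), collapse = ", "),
                         ", custom"))
  }
  if (!length(object@baseLearners)) msg <- c(msg, "base learner list must not be empty")
  bad <- setdiff(object@baseLearners, LEARNER_NAMES)
  if (length(bad)) msg <- c(msg, paste("unknown base learners:", paste(bad, collapse = ", ")))
  if (object@combination %in% names(SM_COMBINATIONS) &&
      !identical(object@baseLearners, SM_COMBINATIONS[[object@combination]])) {
    msg <- c(msg, "baseLearners does not match the named SM combination")
  }
  if (object@nMetaFolds < 2L) msg <- c(msg, "nMetaFolds must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Trained stacked ensemble
#'
#' @slot config the [StackConfig] used for training.
#' @slot fittedBase list of base learners refit on the full training data.
#' @slot fittedMeta gradient-boosted tree meta-classifier fit on
#'   out-of-fold base probabilities.
#' @slot featureLayout the 420 feature names the model expects.
#' @slot fingerprint list: n, class counts, seed, training ids, and a
#'   `degenerateMeta` flag set when any meta-feature column was constant.
#' @export
setClass("StackedModel",
  representation(config = "StackConfig",
                 fittedBase = "list",
                 fittedMeta = "ANY",
                 featureLayout = "character",
                 fingerprint = "list"))

setValidity("StackedModel", function(object) {
  msg <- character()
  if (length(object@fittedBase) != length(object@config@baseLearners)) {
    msg <- c(msg, "one fitted learner required per configured base learner")
  }
  if (length(object@featureLayout) != 420L) msg <- c(msg, "feature layout must have 420 names")
  if (length(msg)) msg else TRUE
})

#' Evaluation report
#'
#' @slot counts named integer vector TP/FP/TN/FN.
#' @slot metrics list with OA, SN, SP, MCC (square-root denominator),
#'   mccLinear (denominator as a plain product), and AUC.
#' @slot roc data.frame of (FPR, TPR) points from (0,0) to (1,1).
#' @slot perSample data.frame: id, label, score, predicted.
#' @slot protocol evaluation protocol descriptor, e.g. `"jackknife"`,
#'   `"kfold(k=5, seed=7)"`, `"independent"`.
#' @export
setClass("EvaluationReport",
  representation(counts = "integer",
                 metrics = "list",
                 roc = "data.frame",
                 perSample = "data.frame",
                 protocol = "character"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (!all(c("TP", "FP", "TN", "FN") %in% names(object@counts))) {
    msg <- c(msg, "counts must contain TP, FP, TN, FN")
  } else if (any(object@counts[c("TP", "FP", "TN", "FN")] < 0L)) {
    msg <- c(msg, "counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic-profile simulation settings
#'
#' @slot nPos,nNeg class sizes.
#' @slot lengthRange (min, max) protein length; minimum length is 2 and the
#'   default range (50, 300) respects the benchmark exclusion of chains
#'   shorter than 50 residues.
#' @slot separation class-separation knob, >= 0; 0 makes the two class
#'   emission distributions identical.
#' @slot starRate probability that an emission entry is replaced by the
#'   STAR marker, in `[0, 1)`.
#' @slot concentration Dirichlet concentration of per-row emission draws.
#' @slot blend first-order blending weight coupling adjacent rows so the
#'   transition features carry class signal beyond composition.
#' @slot seed integer master seed.
#' @export
setClass("SimulationConfig",
  representation(nPos = "integer", nNeg = "integer",
                 lengthRange = "integer", separation = "numeric",
                 starRate = "numeric", concentration = "numeric",
                 blend = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nPos < 0L || object@nNeg < 0L) msg <- c(msg, "class sizes must be >= 0")
  if (length(object@lengthRange) != 2L || object@lengthRange[1L] < 2L ||
      object@lengthRange[2L] < object@lengthRange[1L]) {
    msg <- c(msg, "lengthRange must be (min >= 2, max >= min)")
  }
  if (object@separation < 0) msg <- c(msg, "separation must be >= 0")
  if (object@starRate < 0 || object@starRate >= 1) msg <- c(msg, "starRate must be in [0, 1)")
  if (object@concentration <= 0) msg <- c(msg, "concentration must be > 0")
  if (object@blend < 0 || object@blend >= 1) msg <- c(msg, "blend must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "HMMProfile", function(object) {
  cat("HMMProfile '", object@proteinId, "': L = ", nrow(object@rawScores),
      ", ", sum(is.na(object@rawScores)), " STAR entries\n", sep = "")
})

setMethod("show", "NormalizedProfile", function(object) {
  cat("NormalizedProfile '", object@proteinId, "': L = ", nrow(object@mat),
      ", value range [", signif(min(object@mat), 3), ", ",
      signif(max(object@mat), 3), "]\n", sep = "")
})

setMethod("show", "LabeledDataset", function(object) {
  cat("LabeledDataset: ", length(object@proteinIds), " proteins (",
      sum(object@labels == 1L), " positive, ", sum(object@labels == 0L),
      " negative)\n", sep = "")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix: ", nrow(object@X), " x ", ncol(object@X),
      if (length(object@labels)) " (labeled)" else " (unlabeled)", "\n", sep = "")
})

setMethod("show", "StackConfig", function(object) {
  cat("StackConfig ", object@combination, ": base = {",
      paste(object@baseLearners, collapse = ", "),
      "}, meta = GBDT, nMetaFolds = ", object@nMetaFolds,
      ", seed = ", object@seed, "\n", sep = "")
})

setMethod("show", "StackedModel", function(object) {
  fp <- object@fingerprint
  cat("StackedModel (", object@config@combination, "): trained on n = ", fp$n,
      " (", fp$nPos, "/", fp$nNeg, "), seed = ", fp$seed,
      if (isTRUE(fp$degenerateMeta)) " [degenerate meta-features]" else "",
      "\n", sep = "")
})

setMethod("show", "EvaluationReport", function(object) {
  m <- object@metrics
  fmtPct <- function(x) if (is.na(x)) "NA" else sprintf("%.2f%%", 100 * x)
  fmt4 <- function(x) if (is.na(x)) "NA" else sprintf("%.4f", x)
  cat("EvaluationReport [", object@protocol, "]\n",
      "  counts: TP=", object@counts["TP"], " FP=", object@counts["FP"],
      " TN=", object@counts["TN"], " FN=", object@counts["FN"], "\n",
      "  OA=", fmtPct(m$OA), " SN=", fmtPct(m$SN), " SP=", fmtPct(m$SP),
      " MCC=", fmt4(m$MCC), " AUC=", fmt4(m$AUC), "\n", sep = "")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: ", object@nPos, "+/", object@nNeg, "- proteins, L in [",
      object@lengthRange[1L], ", ", object@lengthRange[2L], "], separation = ",
      object@separation, ", starRate = ", object@starRate,
      ", seed = ", object@seed, "\n", sep = "")
})

## ---- accessors --------------------------------------------------------

#' @rdname accessors
#' @param x an object from this package.
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))
#' @rdname accessors
#' @export
setGeneric("profileLength", function(x) standardGeneric("profileLength"))
#' @rdname accessors
#' @export
setGeneric("rawScores", function(x) standardGeneric("rawScores"))
#' @rdname accessors
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))
#' @rdname accessors
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("reportMetrics", function(x) standardGeneric("reportMetrics"))
#' @rdname accessors
#' @export
setGeneric("reportCounts", function(x) standardGeneric("reportCounts"))
#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setGeneric("perSampleScores", function(x) standardGeneric("perSampleScores"))

#' Accessors for stackDBP objects
#'
#' Small read-only accessors exposing object contents without slot access.
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("proteinId", "HMMProfile", function(x) x@proteinId)
#' @rdname accessors
#' @export
setMethod("proteinId", "NormalizedProfile", function(x) x@proteinId)
#' @rdname accessors
#' @export
setMethod("profileLength", "HMMProfile", function(x) nrow(x@rawScores))
#' @rdname accessors
#' @export
setMethod("profileLength", "NormalizedProfile", function(x) nrow(x@mat))
#' @rdname accessors
#' @export
setMethod("rawScores", "HMMProfile", function(x) x@rawScores)
#' @rdname accessors
#' @export
setMethod("profileMatrix", "NormalizedProfile", function(x) x@mat)
#' @rdname accessors
#' @export
setMethod("alphabet", "HMMProfile", function(x) x@alphabet)
#' @rdname accessors
#' @export
setMethod("alphabet", "NormalizedProfile", function(x) x@alphabet)
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@X)
#' @rdname accessors
#' @export
setMethod("sampleLabels", "FeatureMatrix", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("sampleLabels", "LabeledDataset", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("sampleIds", "FeatureMatrix", function(x) x@ids)
#' @rdname accessors
#' @export
setMethod("sampleIds", "LabeledDataset", function(x) x@proteinIds)
#' @rdname accessors
#' @export
setMethod("reportMetrics", "EvaluationReport", function(x) x@metrics)
#' @rdname accessors
#' @export
setMethod("reportCounts", "EvaluationReport", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("rocPoints", "EvaluationReport", function(x) x@roc)
#' @rdname accessors
#' @export
setMethod("perSampleScores", "EvaluationReport", function(x) x@perSample)

#' Subset a FeatureMatrix by row
#'
#' @param x a [FeatureMatrix].
#' @param i row indices.
#' @param j,drop,... ignored (rows only).
#' @export
setMethod("[", "FeatureMatrix", function(x, i, j, ..., drop = FALSE) {
  new("FeatureMatrix", ids = x@ids[i], X = x@X[i, , drop = FALSE],
      labels = if (length(x@labels)) x@labels[i] else integer(0))
})
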