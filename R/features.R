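## The 420-dimensional AATP encoding of a profile HMM: amino acid
## composition (AAC, 20 per-column means of the normalized emission
## matrix) fused with transition probability composition (TPC, the
## row-normalized 20x20 matrix of summed products of normalized emissions
## at consecutive residue positions).

#' Amino acid composition of a normalized profile
#'
#' For a normalized L x 20 emission matrix `h`, the AAC feature for amino
#' acid type `j` is the column mean `x_j = (1/L) * sum_i h[i, j]`: the
#' average evolutionary propensity of the protein's residues to be
#' substituted by type `j`.
#'
#' @param profile a [NormalizedProfile] with L >= 1.
#' @return named numeric vector of 20 values in `[0, 1]`, in the
#'   profile's stored column order.
#' @export
computeAAC <- function(profile) {
  stopifnot(is(profile, "NormalizedProfile"))
  if (nrow(profile@mat) < 1L) stop("AAC undefined for an empty profile")
  stats::setNames(colMeans(profile@mat), profile@alphabet)
}

#' Transition probability composition of a normalized profile
#'
#' For consecutive residue positions `k` and `k+1`, the unnormalized
#' transition weight from amino acid type `i` to type `j` is
#' `sum_{k=1}^{L-1} h[k, i] * h[k+1, j]`. Each row `i` is then normalized
#' by its total over all `j`, so rows with a positive denominator sum to
#' one. A row whose denominator is zero (type `i` has zero emission
#' probability at every position 1..L-1) is returned as all zeros rather
#' than filled uniformly, preserving "no evidence" as zero signal.
#'
#' @param profile a [NormalizedProfile] with L >= 2.
#' @return 20 x 20 numeric matrix with dimnames from the profile alphabet.
#' @export
computeTPC <- function(profile) {
  stopifnot(is(profile, "NormalizedProfile"))
  h <- profile@mat
  L <- nrow(h)
  if (L < 2L) {
    stop("TPC undefined for profiles with L < 2 (consecutive-pair sums are empty)")
  }
  num <- crossprod(h[-L, , drop = FALSE], h[-1L, , drop = FALSE])
  den <- rowSums(num)
  tpc <- num
  pos <- den > 0
  tpc[pos, ] <- num[pos, , drop = FALSE] / den[pos]
  tpc[!pos, ] <- 0
  dimnames(tpc) <- list(profile@alphabet, profile@alphabet)
  tpc
}

#' Feature names of the 420-dimensional encoding
#'
#' @param alpha the 20-letter column order (default HHsuite order).
#' @return character vector: `AAC_<aa>` (20) then `TPC_<aa_i>_<aa_j>`
#'   (400, row-major: `i` outer, `j` inner).
#' @export
featureNames420 <- function(alpha = HH_ALPHABET) {
  c(paste0("AAC_", alpha),
    paste0("TPC_", rep(alpha, each = 20L), "_", rep(alpha, times = 20L)))
}

#' Encode a profile as a 420-dimensional feature vector
#'
#' Concatenates [computeAAC()] (components 1-20) with the row-major
#' flattening of [computeTPC()] (components 21-420).
#'
#' @param profile a [NormalizedProfile] with L >= 2.
#' @return named numeric vector of length 420.
#' @export
encodeAATP <- function(profile) {
  aac <- computeAAC(profile)
  tpc <- computeTPC(profile)
  stats::setNames(c(aac, as.vector(t(tpc))), featureNames420(profile@alphabet))
}

#' Encode every profile of a labeled dataset
#'
#' @param dataset a [LabeledDataset] whose profiles all have L >= 2.
#' @return a [FeatureMatrix]; row order follows the dataset, labels are
#'   carried through.
#' @export
batchEncode <- function(dataset) {
  stopifnot(is(dataset, "LabeledDataset"))
  n <- length(dataset@proteinIds)
  if (!n) stop("cannot encode an empty dataset")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch(encodeAATP(dataset@profiles[[i]]),
      error = function(e) {
        stop("feature encoding failed for protein '",
             dataset@proteinIds[i], "': ", conditionMessage(e))
      })
  }
  X <- do.call(rbind, rows)
  rownames(X) <- NULL
  new("FeatureMatrix", ids = dataset@proteinIds, X = X, labels = dataset@labels)
}

#' Write a feature matrix as CSV
#'
#' Layout: `id` column, optional `label` column, then the 420 named
#' feature columns.
#'
#' @param fm a [FeatureMatrix].
#' @param sink output CSV path.
#' @return invisibly, the path written.
#' @export
writeFeatureCSV <- function(fm, sink) {
  stopifnot(is(fm, "FeatureMatrix"))
  df <- data.frame(id = fm@ids, stringsAsFactors = FALSE)
  if (length(fm@labels)) df$label <- fm@labels
  df <- cbind(df, as.data.frame(fm@X))
  utils::write.csv(df, sink, row.names = FALSE, quote = TRUE)
  invisible(sink)
}

#' Read a feature matrix CSV written by [writeFeatureCSV()]
#'
#' @param source CSV path.
#' @return a [FeatureMatrix] (labeled when a `label` column is present).
#' @export
readFeatureCSV <- function(source) {
  if (!file.exists(source)) stop("feature CSV not found: ", source)
  df <- utils::read.csv(source, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("feature CSV must contain an 'id' column")
  hasLabel <- "label" %in% names(df)
  featCols <- setdiff(names(df), c("id", "label"))
  if (length(featCols) != 420L) {
    stop("feature CSV must contain exactly 420 feature columns, found ",
         length(featCols))
  }
  X <- as.matrix(df[, featCols])
  if (!is.numeric(X) || anyNA(X)) stop("feature CSV contains non-numeric cells")
  labels <- integer(0)
  if (hasLabel) {
    if (!all(df$label %in% c(0L, 1L))) stop("label column must be 0/1")
    labels <- as.integer(df$label)
  }
  new("FeatureMatrix", ids = as.character(df$id), X = X, labels = labels)
}
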