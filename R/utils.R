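# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# HHsuite column order for the 20 match-emission columns.
HH_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Stratified fold assignment: within each class, members are shuffled and
# dealt cyclically over folds. k == n degenerates to leave-one-out (one
# sample per fold, no stratification possible or needed).
stratifiedFolds <- function(y, k, seed) {
  n <- length(y)
  k <- as.integer(k)
  if (k == n) return(seq_len(n))
  if (k < 2L) stop("number of folds must be >= 2")
  folds <- integer(n)
  withSeed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      if (length(idx) < k) {
        stop("class ", cl, " has ", length(idx),
             " members, fewer than the ", k, " folds required for stratification")
      }
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

# Deterministic per-component seed derivation, kept within 32-bit range.
deriveSeed <- function(seed, ...) {
  offs <- c(...)
  s <- (as.double(seed) + sum(offs * seq_along(offs) * 7919)) %% 2147483647
  as.integer(s)
}

assertBinaryLabels <- function(y, what = "labels") {
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop(what, " must be 0/1 with no missing values")
  }
  invisible(TRUE)
}
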