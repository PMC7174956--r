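# In-code fixtures shared across test files.

# Random raw-score profile with optional STAR entries.
randomHMMProfile <- function(L = 6L, starFrac = 0.1, id = "RND") {
  m <- matrix(sample(0L:6000L, L * 20L, replace = TRUE), nrow = L)
  if (starFrac > 0) m[runif(length(m)) < starFrac] <- NA_integer_
  colnames(m) <- HH20
  new("HMMProfile", proteinId = id,
      residues = paste(sample(HH20, L, replace = TRUE), collapse = ""),
      rawScores = m, alphabet = HH20)
}

# Normalized profile built directly from a numeric matrix in [0, 1].
normProfileFrom <- function(h, id = "NP") {
  colnames(h) <- HH20
  new("NormalizedProfile", proteinId = id,
      residues = paste(rep("A", nrow(h)), collapse = ""),
      mat = h, alphabet = HH20)
}

randomNormalizedProfile <- function(L = 6L, id = "NP") {
  normProfileFrom(matrix(runif(L * 20L), nrow = L), id = id)
}

# Fabricated labeled feature matrix: two Gaussian clouds shifted along
# the first `nInf` feature axes. Cheap stand-in for model-layer tests
# that do not need real profile encodings.
fabricateFM <- function(nPos = 20L, nNeg = 20L, shift = 1.5, nInf = 25L,
                        seed = 1L) {
  set.seed(seed)
  n <- nPos + nNeg
  y <- c(rep(1L, nPos), rep(0L, nNeg))
  X <- matrix(rnorm(n * 420L, sd = 1), nrow = n)
  X[y == 1L, seq_len(nInf)] <- X[y == 1L, seq_len(nInf)] + shift
  colnames(X) <- featureNames420()
  new("FeatureMatrix", ids = sprintf("P%03d", seq_len(n)), X = X, labels = y)
}

# A fast stacked configuration for protocol-level tests: a single
# decision tree base learner and a light meta fit.
fastConfig <- function(seed = 1L, nMetaFolds = 2L) {
  StackConfig("custom", baseLearners = "DT", nMetaFolds = nMetaFolds,
              seed = seed, metaParams = list(nrounds = 20L))
}

# Shared jackknife report on the cached dataset (lazy; jackknife is
# O(n) stacked re-trainings, so compute it once per test run).
.cachedJackknife <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- jackknifeEvaluate(
        StackConfig("SM1", nMetaFolds = 3L, seed = 13L), .cachedEncoded())
    }
    cache
  }
})

# One shared profile-backed dataset for cross-module tests (lazy).
.cachedEncoded <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- SimulationConfig(nPos = 15L, nNeg = 15L,
                              lengthRange = c(50L, 120L),
                              separation = 3, seed = 424L)
      cache <<- batchEncode(generateDataset(cfg, file.path(tempdir(), "ds424")))
    }
    cache
  }
})
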