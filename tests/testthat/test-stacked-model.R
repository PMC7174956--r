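# Two-stage stacked ensemble: configuration, tuning, meta-features,
# training, prediction, serialization.

test_that("named SM combinations fix the base-learner sets", {
  expect_identical(StackConfig("SM1")@baseLearners, c("KNN", "LR", "DT", "SVM_RBF"))
  expect_identical(StackConfig("SM2")@baseLearners, c("KNN", "LR", "DT", "XGB"))
  expect_identical(StackConfig("SM3")@baseLearners, c("KNN", "LR", "DT", "RF"))
  expect_identical(StackConfig("SM4")@baseLearners, c("SVM_RBF", "XGB", "RF"))
  expect_identical(StackConfig("SM5")@baseLearners,
                   c("KNN", "LR", "DT", "SVM_RBF", "RF", "XGB"))
  expect_error(StackConfig("SM9"), "SM1, SM2, SM3, SM4, SM5")
  expect_error(StackConfig("custom"), "non-empty")
  expect_error(StackConfig("custom", baseLearners = "MLP"), "unknown base learners")
})

test_that("grid tuning returns the accuracy-maximizing point, first on ties", {
  fm <- fabricateFM(nPos = 15L, nNeg = 15L, shift = 2.5, seed = 31L)

  # single-point grid comes straight back
  one <- tuneBaseLearner("KNN", fm, grid = list(k = 7L), cvFolds = 3L, seed = 1L)
  expect_identical(one$params$k, 7L)

  # duplicated grid point has identical accuracy; the first is returned
  tie <- tuneBaseLearner("KNN", fm, grid = list(k = c(5L, 5L)), cvFolds = 3L,
                         seed = 1L)
  expect_identical(which.max(tie$table$cv_accuracy), 1L)
  expect_identical(tie$params$k, 5L)

  # leave-one-out grid search over k matches an exhaustive independent
  # re-evaluation with class::knn (LOO is deterministic, so the oracle
  # needs no knowledge of internal fold assignment)
  res <- tuneBaseLearner("KNN", fm, grid = list(k = c(1L, 5L, 15L)),
                         cvFolds = nrow(featureValues(fm)), seed = 1L,
                         standardize = FALSE)
  X <- featureValues(fm); y <- sampleLabels(fm)
  looAcc <- vapply(c(1L, 5L, 15L), function(k) {
    hits <- vapply(seq_len(nrow(X)), function(i) {
      pred <- class::knn(X[-i, , drop = FALSE], X[i, , drop = FALSE],
                         factor(y[-i], levels = c(0L, 1L)), k = k)
      as.integer(as.character(pred)) == y[i]
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_equal(res$table$cv_accuracy, looAcc, tolerance = 1e-12)
  expect_identical(res$params$k, c(1L, 5L, 15L)[which.max(looAcc)])

  expect_error(tuneBaseLearner("KNN", fm, grid = list(), cvFolds = 3L), "empty")
})

test_that("meta-features are out-of-fold, one column per base learner", {
  fm <- fabricateFM(nPos = 12L, nNeg = 12L, shift = 3, seed = 37L)
  cfg <- StackConfig("SM1", nMetaFolds = 3L, seed = 5L)
  M <- generateMetaFeatures(cfg, fm)
  expect_identical(dim(M), c(24L, 4L))
  expect_identical(colnames(M), c("KNN", "LR", "DT", "SVM_RBF"))
  expect_true(all(M >= 0 & M <= 1))
  expect_identical(M, generateMetaFeatures(cfg, fm))  # determinism

  # a perfectly memorizing learner (1-NN) with leave-one-out folds
  # recovers the labels on well-separated data
  memo <- StackConfig("custom", baseLearners = "KNN",
                      baseParams = list(KNN = list(k = 1L)),
                      nMetaFolds = nrow(featureValues(fm)), seed = 5L)
  Mloo <- generateMetaFeatures(memo, fm)
  expect_gte(mean(as.integer(Mloo[, 1] >= 0.5) == sampleLabels(fm)), 0.9)
})

test_that("out-of-fold construction cannot memorize random labels", {
  # Under label noise a 1-NN learner would score 100% by resubstitution;
  # out-of-fold probabilities must stay near chance instead.
  set.seed(43)
  fm <- fabricateFM(nPos = 15L, nNeg = 15L, shift = 0, seed = 43L)
  memo <- StackConfig("custom", baseLearners = "KNN",
                      baseParams = list(KNN = list(k = 1L)),
                      nMetaFolds = nrow(featureValues(fm)), seed = 43L)
  M <- generateMetaFeatures(memo, fm)
  acc <- mean(as.integer(M[, 1] >= 0.5) == sampleLabels(fm))
  expect_lt(acc, 0.8)
})

test_that("stacked training beats or matches every base learner on its training set", {
  fm <- fabricateFM(nPos = 30L, nNeg = 30L, shift = 2.5, seed = 47L)
  cfg <- StackConfig("SM1", nMetaFolds = 5L, seed = 11L)
  model <- trainStacked(cfg, fm)
  expect_s4_class(model, "StackedModel")
  stackedAcc <- mean(predictLabel(model, fm) == sampleLabels(fm))
  for (nm in cfg@baseLearners) {
    lrn <- stackDBP:::fitBaseLearner(nm, featureValues(fm), sampleLabels(fm),
                                     seed = 11L)
    baseAcc <- mean(as.integer(
      stackDBP:::predictBaseLearner(lrn, featureValues(fm)) >= 0.5) ==
      sampleLabels(fm))
    expect_gte(stackedAcc, baseAcc - 1e-12)
  }
})

test_that("training is deterministic given config and data", {
  fm <- fabricateFM(nPos = 10L, nNeg = 10L, shift = 2, seed = 53L)
  cfg <- StackConfig("SM1", nMetaFolds = 2L, seed = 17L)
  m1 <- trainStacked(cfg, fm)
  m2 <- trainStacked(cfg, fm)
  probe <- fabricateFM(nPos = 5L, nNeg = 5L, shift = 0, seed = 99L)
  expect_identical(predictProba(m1, probe), predictProba(m2, probe))
  expect_identical(m1@fingerprint, m2@fingerprint)
})

test_that("predictProba obeys the probability contract and separates classes", {
  fm <- .cachedEncoded()
  cfg <- StackConfig("SM1", nMetaFolds = 3L, seed = 7L)
  model <- trainStacked(cfg, fm)
  p <- predictProba(model, fm)
  expect_length(p, 30L)
  expect_true(all(p >= 0 & p <= 1))
  y <- sampleLabels(fm)
  expect_gt(mean(p[y == 1L]), mean(p[y == 0L]))

  # single-row input yields a single probability
  p1 <- predictProba(model, fm[1])
  expect_length(p1, 1L)
  expect_equal(p1, p[1], tolerance = 1e-12)

  # feature-layout mismatches are named
  bad <- fm
  colnames(bad@X)[3] <- "AAC_bogus"
  expect_error(predictProba(model, bad), "AAC_bogus")
})

test_that("label prediction thresholds probabilities consistently", {
  fm <- .cachedEncoded()
  model <- trainStacked(StackConfig("SM1", nMetaFolds = 3L, seed = 7L), fm)
  p <- predictProba(model, fm)
  for (thr in c(0.1, 0.5, 0.9)) {
    expect_identical(predictLabel(model, fm, thr), as.integer(p >= thr))
  }
  expect_gte(sum(predictLabel(model, fm, 0.1)), sum(predictLabel(model, fm, 0.9)))
  expect_error(predictLabel(model, fm, 0), "strictly inside")
  expect_error(predictLabel(model, fm, 1), "strictly inside")
})

test_that("model serialization round-trips predictions and fingerprint", {
  fm <- fabricateFM(nPos = 8L, nNeg = 8L, shift = 2, seed = 61L)
  cfg <- StackConfig("SM1", nMetaFolds = 2L, seed = 19L)
  model <- trainStacked(cfg, fm)
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(model, f)
  back <- loadModel(f)
  probe <- fabricateFM(nPos = 5L, nNeg = 5L, shift = 1, seed = 77L)
  expect_identical(predictProba(back, probe), predictProba(model, probe))
  expect_identical(back@fingerprint, model@fingerprint)

  # truncated artifact fails loudly
  raw <- readBin(f, "raw", n = file.size(f))
  writeBin(raw[1:20], f)
  expect_error(loadModel(f), "cannot read model file")

  # foreign RDS content is rejected
  saveRDS(list(a = 1), f)
  expect_error(loadModel(f), "not a stackDBP model")
})
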