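# Confusion metrics, ROC/AUC, and the cross-validation drivers.

test_that("confusion counts match the four-branch oracle", {
  expect_identical(confusionCounts(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L)),
                   c(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
  expect_identical(confusionCounts(c(1L, 0L), c(1L, 1L)),
                   c(TP = 1L, FP = 1L, TN = 0L, FN = 0L))
  set.seed(71)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    yt <- sample(0:1, n, replace = TRUE)
    yp <- sample(0:1, n, replace = TRUE)
    expect_identical(confusionCounts(yt, yp), confusionOracle(yt, yp))
  }
  expect_error(confusionCounts(c(1L, 0L), c(1L)), "length")
  expect_error(confusionCounts(c(1L, 2L), c(1L, 0L)), "0/1")
})

test_that("metric formulas agree with direct arithmetic", {
  perfect <- computeMetrics(c(TP = 5L, FP = 0L, TN = 5L, FN = 0L))
  expect_identical(perfect$OA, 1)
  expect_identical(perfect$SN, 1)
  expect_identical(perfect$SP, 1)
  expect_identical(perfect$MCC, 1)

  m <- computeMetrics(c(TP = 3L, FP = 1L, TN = 4L, FN = 2L))
  expect_equal(m$OA, 0.7)
  expect_equal(m$SN, 0.6)
  expect_equal(m$SP, 0.8)
  expect_equal(m$MCC, (3 * 4 - 1 * 2) / sqrt(4 * 5 * 5 * 6), tolerance = 1e-15)
  expect_equal(m$mccLinear, (3 * 4 - 1 * 2) / (4 * 5 * 5 * 6), tolerance = 1e-15)

  # all-positive predictions on a balanced set: zero-denominator rule
  degenerate <- computeMetrics(c(TP = 5L, FP = 5L, TN = 0L, FN = 0L))
  expect_identical(degenerate$MCC, 0)
  expect_identical(degenerate$SP, 0)  # SP = 0/5 is defined, not NA
  # SN undefined when no positives were evaluated
  expect_true(is.na(computeMetrics(c(TP = 0L, FP = 2L, TN = 3L, FN = 0L))$SN))
  expect_error(computeMetrics(c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)), "zero")
})

test_that("metrics match the brute-force oracle on 500 random tables", {
  set.seed(73)
  for (i in 1:500) {
    cc <- c(TP = sample(0:30, 1), FP = sample(0:30, 1),
            TN = sample(0:30, 1), FN = sample(0:30, 1))
    if (sum(cc) == 0) cc["TP"] <- 1L
    got <- computeMetrics(cc)
    want <- metricsOracle(cc)
    expect_equal(got$OA, want$OA, tolerance = 1e-12)
    expect_equal(got$SN, want$SN, tolerance = 1e-12)
    expect_equal(got$SP, want$SP, tolerance = 1e-12)
    expect_equal(got$MCC, want$MCC, tolerance = 1e-12)
  }
})

test_that("ROC endpoints, tie handling and AUC match the pairwise oracle", {
  # perfect separation
  roc <- rocCurve(c(1L, 1L, 0L, 0L), c(0.9, 0.8, 0.2, 0.1))
  expect_identical(roc$auc, 1)
  # all scores tied
  expect_identical(rocCurve(c(1L, 0L, 1L, 0L), rep(0.5, 4))$auc, 0.5)

  set.seed(79)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    y <- c(1L, 0L, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 2)  # rounding forces frequent ties
    r <- rocCurve(y, s)
    expect_equal(r$auc, aucPairOracle(y, s), tolerance = 1e-12)
    expect_identical(unname(unlist(r$points[1, c("FPR", "TPR")])), c(0, 0))
    expect_identical(unname(unlist(r$points[nrow(r$points), c("FPR", "TPR")])),
                     c(1, 1))
    expect_true(all(diff(r$points$FPR) >= 0) && all(diff(r$points$TPR) >= 0))
  }
  expect_error(rocCurve(rep(1L, 4), runif(4)), "both classes")
})

test_that("AUC agrees with pROC and is invariant under monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(83)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    y <- c(1L, 0L, sample(0:1, n - 2, replace = TRUE))
    s <- rnorm(n)
    auc <- rocCurve(y, s)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(auc, ref, tolerance = 1e-12)
    expect_equal(rocCurve(y, exp(2 * s))$auc, auc, tolerance = 1e-12)
    expect_equal(rocCurve(y, rank(s))$auc, auc, tolerance = 1e-12)
  }
})

test_that("k = n fold evaluation reduces exactly to the jackknife", {
  fm <- fabricateFM(nPos = 4L, nNeg = 4L, shift = 2, seed = 89L)
  cfg <- fastConfig(seed = 3L)
  jack <- jackknifeEvaluate(cfg, fm)
  kn <- kfoldEvaluate(cfg, fm, k = 8L)
  expect_identical(jack@protocol, "jackknife")
  expect_identical(perSampleScores(jack)$score, perSampleScores(kn)$score)
  expect_identical(reportCounts(jack), reportCounts(kn))
  expect_identical(sum(reportCounts(jack)), 8L)  # pooled counts sum to n

  expect_error(jackknifeEvaluate(cfg, fm[1:2]), "n >= 3")
  expect_error(jackknifeEvaluate(cfg, fm[c(1, 2, 5)]), "2 members per class")
})

test_that("k-fold evaluation is deterministic and close to the jackknife", {
  fm <- .cachedEncoded()
  cfg <- StackConfig("SM1", nMetaFolds = 3L, seed = 13L)
  r1 <- kfoldEvaluate(cfg, fm, k = 5L)
  r2 <- kfoldEvaluate(cfg, fm, k = 5L)
  expect_identical(perSampleScores(r1)$score, perSampleScores(r2)$score)
  expect_identical(reportMetrics(r1), reportMetrics(r2))
  expect_match(r1@protocol, "kfold\\(k=5")

  jack <- .cachedJackknife()
  expect_gte(reportMetrics(jack)$OA, 0.9)  # strongly separated dataset
  expect_lte(abs(reportMetrics(jack)$OA - reportMetrics(r1)$OA), 0.05)
  expect_identical(sum(reportCounts(jack)), 30L)
})

test_that("independent test reports resubstitution optimism and overlap", {
  fm <- .cachedEncoded()
  cfg <- StackConfig("SM1", nMetaFolds = 3L, seed = 13L)
  model <- trainStacked(cfg, fm)
  expect_warning(rep <- independentTest(model, fm), "not independent")
  expect_identical(rep@protocol, "independent")
  jackOA <- reportMetrics(.cachedJackknife())$OA
  expect_gte(reportMetrics(rep)$OA, jackOA - 1e-12)

  disjoint <- fm[c(1:5, 16:20)]
  disjoint@ids <- paste0("new_", disjoint@ids)
  expect_no_warning(independentTest(model, disjoint))
  expect_error(independentTest(model, fm[integer(0)]), "non-empty")
})

test_that("reports serialize to JSON and TSV with the documented rounding", {
  fm <- fabricateFM(nPos = 5L, nNeg = 5L, shift = 2, seed = 97L)
  rep <- kfoldEvaluate(fastConfig(seed = 5L), fm, k = 2L)
  js <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeReport(rep, jsonPath = js, tsvPath = tsv)
  payload <- jsonlite::read_json(js)
  expect_identical(payload$protocol, rep@protocol)
  expect_equal(payload$metrics$OA_percent, round(100 * reportMetrics(rep)$OA, 2))
  expect_identical(length(payload$per_sample$id), 10L)
  scored <- utils::read.delim(tsv)
  expect_identical(nrow(scored), 10L)
  expect_identical(scored$id, perSampleScores(rep)$id)
})
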