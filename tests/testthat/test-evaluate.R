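test_that("stratified folds balance low/high ADL subjects", {
  counts <- data.frame(subjectId = sprintf("S%02d", 1:10),
                       nFalls = rep(2L, 10),
                       nADLs = c(10, 12, 14, 16, 18, 500, 600, 700, 800, 900))
  fa <- stratifyFolds(counts, k = 5, seed = 3)
  folds <- foldOf(fa)
  expect_setequal(names(folds), counts$subjectId)
  expect_true(all(table(folds) == 2))  # 10 subjects over 5 folds
  low <- counts$subjectId[counts$nADLs <= median(counts$nADLs)]
  high <- setdiff(counts$subjectId, low)
  expect_true(all(table(folds[low]) == 1))
  expect_true(all(table(folds[high]) == 1))
})

test_that("fallers without ADLs are stratified by fall count", {
  counts <- data.frame(subjectId = sprintf("F%02d", 1:10),
                       nFalls = c(1, 1, 2, 2, 3, 8, 9, 10, 11, 12),
                       nADLs = 0L)
  fa <- stratifyFolds(counts, k = 5, seed = 1)
  expect_setequal(unique(fa@strata), c("fall_low", "fall_high"))
  expect_true(all(table(foldOf(fa)) == 2))
})

test_that("fold assignment is an error with fewer subjects than folds", {
  counts <- data.frame(subjectId = letters[1:4], nFalls = 1L, nADLs = 1L)
  expect_error(stratifyFolds(counts, k = 5), "at least as many subjects")
})

test_that("duplicated subjects across folds are rejected", {
  folds <- c(a = 1L, b = 2L, a = 3L)
  expect_error(new("FoldAssignment", folds = folds, k = 3L,
                   strata = c(a = "adl_low", b = "adl_low", a = "adl_low"),
                   seed = 1L),
               "exactly one fold")
})

test_that("fold assignment is deterministic in the seed", {
  counts <- data.frame(subjectId = sprintf("S%02d", 1:12),
                       nFalls = rep(1:3, 4), nADLs = rep(c(0L, 5L), 6))
  expect_identical(foldOf(stratifyFolds(counts, seed = 9)),
                   foldOf(stratifyFolds(counts, seed = 9)))
  expect_false(identical(foldOf(stratifyFolds(counts, seed = 9)),
                         foldOf(stratifyFolds(counts, seed = 10))))
})

test_that("metrics match direct formula evaluation", {
  scores <- c(rep(1, 8), rep(0, 2), rep(1, 10), rep(0, 980))
  labels <- c(rep("fall", 10), rep("adl", 990))
  m <- computeMetrics(scores, labels, monitoredHours = 2)
  expect_identical(c(m@tp, m@fn, m@fp, m@tn), c(8L, 2L, 10L, 980L))
  expect_equal(m@sensitivity, 0.800, tolerance = 1e-12)
  expect_equal(m@specificity, 0.9899, tolerance = 1e-4)
  expect_equal(round(m@ppv, 4), 0.4444)
  expect_equal(round(m@fMeasure, 4), 0.5714)
  expect_equal(m@faPerHour, 5.0)
})

test_that("published sensitivity and precision reproduce the published F", {
  expect_equal(2 * 0.811 * 0.537 / (0.811 + 0.537), 0.646, tolerance = 5e-4)
})

test_that("the F-measure is the harmonic mean of its own report fields", {
  withr::with_seed(51, {
    for (rep in 1:20) {
      n <- 50
      scores <- runif(n)
      labels <- sample(c("fall", "adl"), n, replace = TRUE,
                       prob = c(0.3, 0.7))
      if (length(unique(labels)) < 2) next
      m <- computeMetrics(scores, labels, monitoredHours = 1.5)
      if (is.na(m@fMeasure)) next
      expect_equal(m@fMeasure,
                   2 * m@ppv * m@sensitivity / (m@ppv + m@sensitivity),
                   tolerance = 1e-12)
      expect_equal(m@faPerHour * m@monitoredHours, m@fp, tolerance = 1e-9)
    }
  })
})

test_that("undefined ratios are reported as NA, never zero", {
  # no positives and no predicted positives: sensitivity and PPV undefined
  m <- computeMetrics(c(0.1, 0.2), c("adl", "adl"), monitoredHours = 1)
  expect_true(is.na(m@sensitivity))
  expect_true(is.na(m@ppv))
  expect_true(is.na(m@fMeasure))
  expect_equal(m@faPerHour, 0)  # no false positives -> 0 alarms per hour
})

test_that("ROC AUC equals the Mann-Whitney concordance", {
  expect_equal(rocAUC(c(0, 0, 1, 1), c("adl", "adl", "fall", "fall")), 1)
  expect_equal(rocAUC(rep(0.4, 6), rep(c("fall", "adl"), 3)), 0.5)
  expect_equal(rocAUC(c(0.9, 0.8, 0.4, 0.1), c("fall", "adl", "fall", "adl")),
               0.75)
  expect_error(rocAUC(c(0.1, 0.2), c("adl", "adl")), "both classes")
  withr::with_seed(52, {
    for (rep in 1:15) {
      n <- sample(20:200, 1)
      scores <- round(runif(n), 2)  # induce ties
      labels <- sample(c("fall", "adl"), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      expect_equal(rocAUC(scores, labels), oracleAUC(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("rank-based AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(53, {
    scores <- runif(80)
    labels <- sample(c("fall", "adl"), 80, replace = TRUE)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = factor(labels, levels = c("adl", "fall")),
      predictor = scores, quiet = TRUE, direction = "<")))
    expect_equal(rocAUC(scores, labels), ref, tolerance = 1e-12)
  })
})

test_that("cross-validation conserves windows and rebuilds templates", {
  ds <- sharedDataset()
  res <- runCV(ds$recordings, classifierSpec("naive_bayes"),
               featureSet = "multiphase", seed = 1)
  col <- collectCFWs(ds$recordings)
  lab <- vapply(col$cfws, cfwLabel, character(1))
  m <- res$pooled
  expect_equal(m@tp + m@fn,
               sum(lab == "fall") + length(col$missedFallSubjects))
  expect_equal(m@tp + m@fp + m@tn + m@fn,
               length(col$cfws) + length(col$missedFallSubjects))
  expect_equal(m@monitoredHours, col$monitoredHours)
  # per-fold templates differ because training falls differ
  tmplVals <- lapply(res$templates, slot, "values")
  expect_gt(length(unique(tmplVals)), 1)
  # test scores cover every CFW exactly once
  expect_equal(nrow(res$scores), length(col$cfws))
})

test_that("a fast classifier reaches high sensitivity on easy synthetic data", {
  ds <- sharedDataset()
  res <- runCV(ds$recordings, classifierSpec("naive_bayes"),
               featureSet = "multiphase", seed = 1)
  expect_gte(res$pooled@sensitivity, 0.9)
  expect_gte(res$pooled@auc, 0.95)
})

test_that("the baseline runs on the same candidate set as the classifiers", {
  ds <- sharedDataset()
  bl <- runKangasBaseline(ds$recordings)
  col <- collectCFWs(ds$recordings)
  expect_equal(nrow(bl$detections), length(col$cfws))
  m <- bl$pooled
  expect_true(is.na(m@auc))  # binary detector: single operating point
  expect_equal(m@tp + m@fp + m@tn + m@fn,
               length(col$cfws) + length(col$missedFallSubjects))
})
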