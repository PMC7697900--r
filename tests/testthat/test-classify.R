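test_that("undersampling keeps all falls and the requested ADL fraction", {
  tab <- toyFeatureTable(nPerClass = 25)
  big <- rbind(tab, do.call(rbind, replicate(40, tab[tab$label == "adl", ],
                                             simplify = FALSE)))
  attr(big, "featureSet") <- "multiphase"
  nFall <- sum(big$label == "fall")
  nAdl <- sum(big$label == "adl")
  red <- undersampleMajority(big, 0.1, seed = 5)
  expect_equal(sum(red$label == "fall"), nFall)
  expect_equal(sum(red$label == "adl"), round(0.1 * nAdl))
  expect_identical(undersampleMajority(big, 0.1, seed = 5), red)
  expect_equal(nrow(undersampleMajority(big, 1, seed = 5)), nrow(big))
  red2 <- undersampleMajority(big, 0.1, seed = 6)
  expect_false(identical(red2, red))
})

test_that("3-NN scores are neighbour fractions on a hand-checkable set", {
  # 1-D feature, points far apart: the 3 nearest neighbours (excluding the
  # query itself at training time, including it at prediction) are evident
  fn <- featureNames("multiphase")
  x <- c(0, 1, 2, 10, 11, 12, 20, 21, 29, 33)
  lab <- c("adl", "adl", "adl", "fall", "fall", "fall", "adl", "fall",
           "fall", "fall")
  tab <- data.frame(subjectId = sprintf("T%d", 1:10),
                    recordingId = sprintf("r%d", 1:10),
                    peakSample = 1:10 * 100L, label = lab,
                    matrix(rep(x, length(fn)), ncol = length(fn),
                           dimnames = list(NULL, fn)),
                    check.names = FALSE)
  attr(tab, "featureSet") <- "multiphase"
  spec <- classifierSpec("knn", undersampleFraction = 1)
  det <- trainDetector(spec, tab, seed = 1)
  sc <- predictScores(det, tab)
  expect_true(all(sc %in% c(0, 1/3, 2/3, 1)))
  # each point's own 3-NN neighbourhood (the point itself plus 2 nearest)
  expect_equal(sc, c(0, 0, 0, 1, 1, 1, 2/3, 2/3, 1, 1))
})

test_that("standardization parameters come from the training rows", {
  tab <- toyFeatureTable()
  spec <- classifierSpec("svm_rbf", svmCGrid = 1, svmGammaGrid = 0.1,
                         undersampleFraction = 1)
  det <- trainDetector(spec, tab, seed = 1)
  cols <- featureNames("multiphase")
  m <- as.matrix(tab[, cols])
  expect_equal(unname(det@center), unname(colMeans(m)), tolerance = 1e-12)
  expect_equal(unname(det@scale), unname(apply(m, 2, sd)), tolerance = 1e-12)
  z <- sweep(sweep(m, 2, det@center, "-"), 2, det@scale, "/")
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
})

test_that("the SVM grid has the published cardinality", {
  spec <- classifierSpec("svm_rbf")
  expect_length(spec@svmCGrid, 21)
  expect_length(spec@svmGammaGrid, 19)
  expect_equal(length(spec@svmCGrid) * length(spec@svmGammaGrid), 399)
})

test_that("grid search returns the single pair of a degenerate grid", {
  tab <- toyFeatureTable()
  spec <- classifierSpec("svm_rbf", svmCGrid = 4, svmGammaGrid = 0.25,
                         undersampleFraction = 1)
  sel <- svmGridSearch(tab, spec, seed = 1)
  expect_equal(unname(sel["C"]), 4)
  expect_equal(unname(sel["gamma"]), 0.25)
})

test_that("grid search reaches perfect internal accuracy on separable data", {
  tab <- toyFeatureTable(nPerClass = 15, sep = 6)
  spec <- classifierSpec("svm_rbf", svmCGrid = 2^(0:3),
                         svmGammaGrid = 2^(-4:0), undersampleFraction = 1)
  sel <- svmGridSearch(tab, spec, seed = 1)
  expect_equal(attr(sel, "accuracy"), 1)
})

test_that("grid search warns and falls back with too few subjects", {
  tab <- toyFeatureTable(nSubjects = 3)
  spec <- classifierSpec("svm_rbf", svmCGrid = 1, svmGammaGrid = 0.1,
                         undersampleFraction = 1)
  expect_warning(svmGridSearch(tab, spec, seed = 1), "record-level")
})

test_that("the random forest uses the configured number of trees", {
  tab <- toyFeatureTable()
  det <- trainDetector(classifierSpec("random_forest",
                                      undersampleFraction = 1), tab, seed = 1)
  expect_equal(det@model$ntree, 20)
})

test_that("training is deterministic given the seed", {
  tab <- toyFeatureTable(nPerClass = 20)
  probe <- toyFeatureTable(nPerClass = 8, seed = 99)
  for (fam in c("naive_bayes", "logistic_regression", "knn",
                "random_forest")) {
    s1 <- predictScores(trainDetector(classifierSpec(fam), tab, seed = 3),
                        probe)
    s2 <- predictScores(trainDetector(classifierSpec(fam), tab, seed = 3),
                        probe)
    expect_identical(s1, s2)
  }
  spec <- classifierSpec("svm_rbf", svmCGrid = 2^(0:2),
                         svmGammaGrid = 2^(-2:0))
  expect_identical(
    predictScores(trainDetector(spec, tab, seed = 3), probe),
    predictScores(trainDetector(spec, tab, seed = 3), probe))
})

test_that("scores live in [0, 1] and separate a separable toy set", {
  tab <- toyFeatureTable(nPerClass = 20, sep = 5)
  probe <- toyFeatureTable(nPerClass = 10, sep = 5, seed = 7)
  for (fam in c("naive_bayes", "logistic_regression", "knn",
                "random_forest", "svm_rbf")) {
    spec <- if (fam == "svm_rbf")
      classifierSpec(fam, svmCGrid = 2^(0:4), svmGammaGrid = 2^(-4:0),
                     undersampleFraction = 1)
    else classifierSpec(fam, undersampleFraction = 1)
    det <- trainDetector(spec, tab, seed = 2)
    sc <- predictScores(det, probe)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_gt(min(sc[probe$label == "fall"]), max(sc[probe$label == "adl"]))
  }
})

test_that("empty tables score to empty vectors and mismatches error", {
  tab <- toyFeatureTable()
  det <- trainDetector(classifierSpec("naive_bayes", undersampleFraction = 1),
                       tab, seed = 1)
  expect_identical(predictScores(det, tab[0, ]), numeric(0))
  bad <- toyFeatureTable(featureSet = "conventional")
  expect_error(predictScores(det, bad[, 1:6]), "feature columns")
})

test_that("single-class training sets are rejected", {
  tab <- toyFeatureTable()
  expect_error(trainDetector(classifierSpec("naive_bayes"),
                             tab[tab$label == "adl", ], seed = 1),
               "both classes")
})
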