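#' Construct a ClassifierSpec
#'
#' Defaults follow the published study configuration: 3 nearest neighbours,
#' 20 random-forest trees (regression mode, so scores are ensemble means in
#' \[0, 1\]), RBF-SVM grids `C = 2^-5 .. 2^15` and `gamma = 2^-15 .. 2^3`
#' (399 pairs), feature standardization for KNN and SVM, and undersampling of
#' the majority (ADL) class to 10% in the training set.
#'
#' @param family classifier family; see [ClassifierSpec-class].
#' @param knnK,rfTrees,svmCGrid,svmGammaGrid,undersampleFraction
#'   hyperparameters; see [ClassifierSpec-class].
#' @param standardize default follows the family (TRUE for knn and svm_rbf).
#' @return a validated [ClassifierSpec-class].
#' @export
classifierSpec <- function(family = c("svm_rbf", "naive_bayes",
                                      "logistic_regression", "knn",
                                      "random_forest"),
                           knnK = 3, rfTrees = 20,
                           svmCGrid = 2^(-5:15), svmGammaGrid = 2^(-15:3),
                           standardize = NULL, undersampleFraction = 0.10) {
  family <- match.arg(family)
  if (is.null(standardize)) standardize <- family %in% c("knn", "svm_rbf")
  new("ClassifierSpec", family = family, knnK = as.integer(knnK),
      rfTrees = as.integer(rfTrees), svmCGrid = as.numeric(svmCGrid),
      svmGammaGrid = as.numeric(svmGammaGrid), standardize = standardize,
      undersampleFraction = undersampleFraction)
}

setMethod("show", "ClassifierSpec", function(object) {
  cat(sprintf(
    "ClassifierSpec: %s (standardize=%s, undersample=%.2f)\n", object@family,
    object@standardize, object@undersampleFraction))
  if (object@family == "svm_rbf")
    cat(sprintf("  grid: %d C values x %d gamma values = %d pairs\n",
                length(object@svmCGrid), length(object@svmGammaGrid),
                length(object@svmCGrid) * length(object@svmGammaGrid)))
})

#' Undersample the majority (ADL) class of a feature table
#'
#' Keeps every fall row and a uniformly drawn (without replacement) fraction
#' of the ADL rows, to counter the heavy class imbalance of continuous
#' monitoring. Applied to training data only; test folds are never
#' undersampled.
#'
#' @param table a feature table from [extractFeatures()] containing both
#'   labels.
#' @param fraction fraction of ADL rows retained (default 0.10).
#' @param seed integer seed making the draw reproducible.
#' @return the reduced feature table (row order: original order preserved).
#' @export
undersampleMajority <- function(table, fraction = 0.10, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  adl <- which(table$label == "adl")
  keepN <- round(fraction * length(adl))
  keep <- withr::with_seed(as.integer(seed),
                           adl[sample.int(length(adl), keepN)])
  out <- table[sort(c(which(table$label == "fall"), keep)), , drop = FALSE]
  attr(out, "featureSet") <- attr(table, "featureSet")
  rownames(out) <- NULL
  out
}

# standardized numeric feature matrix in a fixed column order
.featMatrix <- function(table, cols, center = NULL, scale = NULL) {
  m <- as.matrix(table[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  if (!is.null(center)) m <- sweep(m, 2, center, "-")
  if (!is.null(scale)) m <- sweep(m, 2, scale, "/")
  m
}

# internal: fit one RBF SVM and return predicted labels for newx
.svmFitPredict <- function(x, y, C, gamma, newx) {
  fit <- e1071::svm(x = x, y = y, type = "C-classification",
                    kernel = "radial", cost = C, gamma = gamma, scale = FALSE)
  stats::predict(fit, newx)
}

#' Grid search for RBF-SVM hyperparameters
#'
#' Evaluates every (C, gamma) pair of the spec's exponential grids by internal
#' k-fold subject-based cross-validation accuracy on the (already
#' undersampled) training table and returns the argmax. Ties are broken by the
#' smaller C, then the smaller gamma, preferring smoother models. With fewer
#' training subjects than folds the internal split falls back to record-level
#' folds with a warning.
#'
#' @param train training feature table with both labels.
#' @param spec a [ClassifierSpec-class].
#' @param k internal folds (default 5).
#' @param seed seed for the internal fold shuffle.
#' @return named numeric vector `c(C = ..., gamma = ...)` with attribute
#'   `accuracy` (the best internal CV accuracy).
#' @export
svmGridSearch <- function(train, spec = classifierSpec("svm_rbf"), k = 5,
                          seed = 1) {
  stopifnot(all(c("fall", "adl") %in% train$label))
  cols <- featureColumns(train)
  ctr <- colMeans(train[, cols, drop = FALSE])
  scl <- apply(train[, cols, drop = FALSE], 2, stats::sd)
  scl[scl == 0] <- 1
  x <- .featMatrix(train, cols, ctr, scl)
  y <- factor(train$label, levels = c("adl", "fall"))

  subj <- unique(train$subjectId)
  if (length(subj) >= k) {
    counts <- .subjectCounts(train)
    fa <- stratifyFolds(counts, k = k, seed = seed)
    foldOf <- fa@folds[train$subjectId]
  } else {
    warning("fewer than ", k,
            " training subjects; falling back to record-level internal folds")
    foldOf <- withr::with_seed(as.integer(seed),
                               sample(rep_len(seq_len(k), nrow(train))))
  }

  best <- c(C = NA_real_, gamma = NA_real_)
  bestAcc <- -Inf
  for (C in sort(spec@svmCGrid)) {
    for (g in sort(spec@svmGammaGrid)) {
      correct <- 0L
      for (f in sort(unique(foldOf))) {
        tr <- foldOf != f
        if (length(unique(y[tr])) < 2L) next
        pred <- .svmFitPredict(x[tr, , drop = FALSE], y[tr], C, g,
                               x[!tr, , drop = FALSE])
        correct <- correct + sum(pred == y[!tr])
      }
      acc <- correct / nrow(train)
      if (acc > bestAcc + 1e-12) {  # strict improvement: ties keep smaller C, gamma
        bestAcc <- acc
        best <- c(C = C, gamma = g)
      }
    }
  }
  structure(best, accuracy = bestAcc)
}

#' Train a fall detector
#'
#' Applies majority-class undersampling, derives standardization parameters
#' from the (reduced) training rows when the spec demands, runs the SVM grid
#' search for the `svm_rbf` family, and fits the model. All randomness flows
#' from `seed`, so identical inputs give bit-identical detectors.
#'
#' Score definitions by family: posterior probability of the fall class
#' (naive Bayes, logistic regression), fall-neighbour fraction (KNN), mean of
#' per-tree regression outputs (random forest), and a Platt-calibrated
#' probability from the decision values (SVM). All live in \[0, 1\] so a
#' common 0.5 threshold and ROC analysis apply.
#'
#' @param spec a [ClassifierSpec-class].
#' @param train training feature table with both labels.
#' @param seed integer seed.
#' @param template the [MotherWaveletTemplate-class] used when extracting the
#'   training features (stored for provenance; `NULL` for conventional
#'   features).
#' @return a [TrainedDetector-class].
#' @export
trainDetector <- function(spec, train, seed = 1, template = NULL) {
  stopifnot(is(spec, "ClassifierSpec"))
  if (length(unique(train$label)) < 2L)
    stop("training set must contain both classes")
  train <- undersampleMajority(train, spec@undersampleFraction, seed = seed)
  cols <- featureColumns(train)
  ctr <- scl <- numeric(0)
  if (spec@standardize) {
    ctr <- colMeans(train[, cols, drop = FALSE])
    scl <- apply(train[, cols, drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
  }
  x <- .featMatrix(train, cols,
                   if (spec@standardize) ctr else NULL,
                   if (spec@standardize) scl else NULL)
  y <- factor(train$label, levels = c("adl", "fall"))
  y01 <- as.numeric(y == "fall")
  svmC <- svmGamma <- NA_real_
  platt <- numeric(0)

  model <- switch(spec@family,
    naive_bayes = e1071::naiveBayes(x = as.data.frame(x), y = y),
    logistic_regression = {
      df <- data.frame(.y = y01, x, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    knn = list(x = x, y = y),  # lazy learner: memorize training data
    # regression mode on the 0/1 label gives continuous ensemble-mean scores;
    # the forest's "are you sure" note about few unique responses is expected
    random_forest = withr::with_seed(as.integer(seed), suppressWarnings(
      randomForest::randomForest(x = x, y = y01, ntree = spec@rfTrees))),
    svm_rbf = {
      if (length(spec@svmCGrid) * length(spec@svmGammaGrid) > 1L) {
        sel <- svmGridSearch(train, spec, seed = seed)
        svmC <- sel[["C"]]; svmGamma <- sel[["gamma"]]
      } else {
        svmC <- spec@svmCGrid; svmGamma <- spec@svmGammaGrid
      }
      fit <- e1071::svm(x = x, y = y, type = "C-classification",
                        kernel = "radial", cost = svmC, gamma = svmGamma,
                        scale = FALSE)
      dvm <- attr(stats::predict(fit, x, decision.values = TRUE),
                  "decision.values")
      # orient decision values so larger means "fall"
      sgn <- if (startsWith(colnames(dvm)[1L], "fall")) 1 else -1
      dv <- dvm[, 1L]
      cal <- suppressWarnings(stats::glm(y01 ~ dv,
                                         data = data.frame(y01 = y01,
                                                           dv = sgn * dv),
                                         family = stats::binomial()))
      platt <- stats::coef(cal)
      platt <- c(platt, sign = sgn)
      fit
    })

  new("TrainedDetector", model = model, spec = spec,
      featureSet = attr(train, "featureSet") %||% "multiphase",
      featureNames = cols, center = ctr, scale = scl,
      template = template, svmC = svmC, svmGamma = svmGamma, platt = platt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "TrainedDetector", function(object) {
  cat(sprintf("TrainedDetector: %s on %s features (%d columns)\n",
              object@spec@family, object@featureSet,
              length(object@featureNames)))
  if (object@spec@family == "svm_rbf")
    cat(sprintf("  selected C = %g, gamma = %g\n", object@svmC,
                object@svmGamma))
})

#' Score feature rows with a trained detector
#'
#' Returns one fall score in \[0, 1\] per row; thresholding (0.5 in the
#' published evaluation) is the caller's concern.
#'
#' @param detector a [TrainedDetector-class].
#' @param table a feature table whose feature columns match training.
#' @return numeric vector of scores in \[0, 1\] (length 0 for empty tables).
#' @export
predictScores <- function(detector, table) {
  stopifnot(is(detector, "TrainedDetector"))
  cols <- detector@featureNames
  if (!all(cols %in% names(table)))
    stop("feature columns do not match the detector's training features")
  if (!nrow(table)) return(numeric(0))
  x <- .featMatrix(table, cols,
                   if (length(detector@center)) detector@center else NULL,
                   if (length(detector@scale)) detector@scale else NULL)
  spec <- detector@spec
  scores <- switch(spec@family,
    naive_bayes = stats::predict(detector@model, as.data.frame(x),
                                 type = "raw")[, "fall"],
    logistic_regression = {
      df <- as.data.frame(x)
      as.numeric(stats::predict(detector@model, newdata = df,
                                type = "response"))
    },
    knn = {
      pred <- class::knn(detector@model$x, x, detector@model$y,
                         k = spec@knnK, prob = TRUE, use.all = TRUE)
      p <- attr(pred, "prob")  # fraction of votes for the winning class
      ifelse(pred == "fall", p, 1 - p)
    },
    random_forest = as.numeric(stats::predict(detector@model, x)),
    svm_rbf = {
      dv <- attr(stats::predict(detector@model, x, decision.values = TRUE),
                 "decision.values")[, 1L]
      eta <- detector@platt[["(Intercept)"]] +
        detector@platt[["dv"]] * (detector@platt[["sign"]] * dv)
      1 / (1 + exp(-eta))
    })
  pmin(pmax(as.numeric(scores), 0), 1)
}
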