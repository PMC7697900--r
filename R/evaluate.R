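# per-subject fall/ADL counts from any data.frame with subjectId + label
.subjectCounts <- function(table) {
  subs <- unique(table$subjectId)
  data.frame(
    subjectId = subs,
    nFalls = vapply(subs, function(s)
      sum(table$subjectId == s & table$label == "fall"), integer(1)),
    nADLs = vapply(subs, function(s)
      sum(table$subjectId == s & table$label == "adl"), integer(1)),
    row.names = NULL)
}

#' Stratified subject-based cross-validation folds
#'
#' Assigns whole subjects to folds so that no individual contributes data to
#' both training and test sets. Subjects with ADL windows are split at the
#' median ADL count into low/high groups; each group is shuffled (by `seed`)
#' and dealt round-robin over the folds, so every fold gets a balanced share
#' of low- and high-activity subjects. The remaining subjects (fallers without
#' ADLs) are likewise split at the median fall count and dealt round-robin.
#'
#' @param counts data.frame with columns `subjectId`, `nFalls`, `nADLs`
#'   (one row per subject).
#' @param k number of folds (default 5).
#' @param seed integer seed for the within-stratum shuffles.
#' @return a validated [FoldAssignment-class].
#' @export
stratifyFolds <- function(counts, k = 5, seed = 1) {
  stopifnot(all(c("subjectId", "nFalls", "nADLs") %in% names(counts)))
  if (anyDuplicated(counts$subjectId))
    stop("duplicated subject ids in counts")
  if (nrow(counts) < k)
    stop("need at least as many subjects (", nrow(counts), ") as folds (",
         k, ")")
  k <- as.integer(k)
  folds <- integer(0)
  strata <- character(0)
  withAdl <- counts[counts$nADLs > 0, , drop = FALSE]
  fallOnly <- counts[counts$nADLs == 0, , drop = FALSE]

  assignStratum <- function(ids, label) {
    if (!length(ids)) return()
    ids <- withr::with_seed(as.integer(seed) + length(folds),
                            sample(ids))
    f <- rep_len(seq_len(k), length(ids))
    folds[ids] <<- f
    strata[ids] <<- label
  }
  if (nrow(withAdl)) {
    med <- stats::median(withAdl$nADLs)
    assignStratum(withAdl$subjectId[withAdl$nADLs <= med], "adl_low")
    assignStratum(withAdl$subjectId[withAdl$nADLs > med], "adl_high")
  }
  if (nrow(fallOnly)) {
    med <- stats::median(fallOnly$nFalls)
    assignStratum(fallOnly$subjectId[fallOnly$nFalls <= med], "fall_low")
    assignStratum(fallOnly$subjectId[fallOnly$nFalls > med], "fall_high")
  }
  new("FoldAssignment", folds = folds, k = k, strata = strata,
      seed = as.integer(seed))
}

#' @rdname FoldAssignment-class
#' @param x a `FoldAssignment`.
#' @export
foldOf <- function(x) x@folds

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d subjects over %d folds (seed %d)\n",
              length(object@folds), object@k, object@seed))
  print(table(stratum = object@strata, fold = object@folds))
})

#' Area under the ROC curve
#'
#' AUC over all score thresholds, computed as the Mann-Whitney concordance
#' probability: the chance a random fall row scores above a random ADL row,
#' ties counting one half. This equals the trapezoidal area under the ROC
#' curve.
#'
#' @param scores numeric scores (higher means more fall-like).
#' @param labels parallel labels (`"fall"`/`"adl"`, or logical with `TRUE` =
#'   fall).
#' @return AUC in \[0, 1\].
#' @export
rocAUC <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "fall"
  stopifnot(length(scores) == length(pos))
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0L || nneg == 0L)
    stop("AUC requires both classes to be present")
  r <- rank(scores)  # average ranks implement the ties-count-half convention
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Compute a MetricsReport from scores and labels
#'
#' Applies the score threshold (default 0.5; a score `>= threshold` predicts a
#' fall), builds the confusion counts, and derives sensitivity, specificity,
#' PPV, F-measure (harmonic mean of sensitivity and PPV), false alarms per
#' monitored hour (`FP / monitoredHours`) and AUC. Falls whose recordings
#' yielded no CFW are passed via `nMissedFalls` and counted as false
#' negatives. Undefined ratios are reported as `NA`, never 0.
#'
#' @param scores numeric scores in \[0, 1\].
#' @param labels parallel labels (`"fall"`/`"adl"` or logical).
#' @param monitoredHours total ADL hours, the denominator of FA/h.
#' @param threshold score threshold (default 0.5).
#' @param nMissedFalls falls with no candidate window (extra FNs).
#' @param computeAUC set `FALSE` for binary detectors whose single operating
#'   point makes the AUC uninformative.
#' @return a [MetricsReport-class].
#' @export
computeMetrics <- function(scores, labels, monitoredHours, threshold = 0.5,
                           nMissedFalls = 0L, computeAUC = TRUE) {
  stopifnot(monitoredHours > 0, length(scores) == length(labels))
  pos <- if (is.logical(labels)) labels else labels == "fall"
  pred <- scores >= threshold
  tp <- sum(pred & pos)
  fp <- sum(pred & !pos)
  tn <- sum(!pred & !pos)
  fn <- sum(!pred & pos) + as.integer(nMissedFalls)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spc <- ratio(tn, tn + fp)
  ppv <- ratio(tp, tp + fp)
  f <- if (!is.na(sens) && !is.na(ppv) && (sens + ppv) > 0)
    2 * ppv * sens / (ppv + sens) else NA_real_
  auc <- if (computeAUC && any(pos) && any(!pos) && length(scores))
    rocAUC(scores, pos) else NA_real_
  new("MetricsReport", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn),
      sensitivity = sens, specificity = spc, ppv = ppv, fMeasure = f,
      faPerHour = fp / monitoredHours, auc = auc,
      monitoredHours = monitoredHours, threshold = threshold)
}

#' @rdname MetricsReport-class
#' @param report a `MetricsReport`.
#' @return `metricsAsList()`: a plain named list (for JSON serialization).
#' @export
metricsAsList <- function(report) {
  list(tp = report@tp, fp = report@fp, tn = report@tn, fn = report@fn,
       sensitivity = report@sensitivity, specificity = report@specificity,
       ppv = report@ppv, f_measure = report@fMeasure,
       fa_per_hour = report@faPerHour, auc = report@auc,
       monitored_hours = report@monitoredHours, threshold = report@threshold)
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    paste0("MetricsReport (threshold %.2f): TP=%d FP=%d TN=%d FN=%d\n",
           "  sensitivity %.3f | specificity %.3f | PPV %.3f | F %.3f\n",
           "  FA/h %.3f over %.2f monitored hours | AUC %s\n"),
    object@threshold, object@tp, object@fp, object@tn, object@fn,
    object@sensitivity, object@specificity, object@ppv, object@fMeasure,
    object@faPerHour, object@monitoredHours,
    ifelse(is.na(object@auc), "-", sprintf("%.3f", object@auc))))
})

#' Extract candidate fall windows from a dataset of recordings
#'
#' Runs the full segmentation front end over a list of recordings: clip each
#' recording to the common dynamic range, compute the norm, find CFWs, keep
#' the single CFW nearest the annotated impact for fall recordings (falls with
#' no CFW are recorded as missed) and all CFWs for ADL recordings. Monitored
#' hours accumulate the ADL recording durations only.
#'
#' @param recordings list of [TriaxialRecording-class].
#' @param cfg a [WindowingConfig-class].
#' @param clipLimitG common dynamic range in g (default 2).
#' @return list with `cfws` (list of CFWs), `missedFallSubjects` (character,
#'   one entry per missed fall), `monitoredHours`, and `adlHoursBySubject`
#'   (named numeric).
#' @export
collectCFWs <- function(recordings, cfg = windowingConfig(), clipLimitG = 2) {
  cfws <- list()
  missed <- character(0)
  adlHours <- numeric(0)
  for (rec in recordings) {
    rec2 <- clipToRange(rec, clipLimitG)
    w <- findCFWs(computeNorm(rec2), rec2, cfg)
    if (recordingKind(rec) == "fall") {
      sel <- selectFallCFW(w, impactSample(rec))
      if (is.null(sel)) missed <- c(missed, subjectId(rec))
      else cfws <- c(cfws, list(sel))
    } else {
      h <- nSamples(rec) / samplingRate(rec) / 3600
      s <- subjectId(rec)
      adlHours[s] <- (if (s %in% names(adlHours)) adlHours[[s]] else 0) + h
      cfws <- c(cfws, selectADLCFWs(w))
    }
  }
  list(cfws = cfws, missedFallSubjects = missed,
       monitoredHours = sum(adlHours), adlHoursBySubject = adlHours)
}

.deriveSeed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 131 + salt) %% 2147483647)
}

#' Run the stratified subject-based cross-validation pipeline
#'
#' For each fold: the mother-wavelet template is built from the training-fold
#' falls only, features are extracted for training and test CFWs with that
#' template, training ADLs are undersampled, the classifier is fitted, and the
#' untouched test fold is scored. Headline metrics pool the confusion counts
#' of all test folds (the only scheme under which FA/h = FP / total monitored
#' hours is coherent); per-fold reports are also returned. Falls that produced
#' no CFW count as false negatives in their subject's fold.
#'
#' @param recordings list of [TriaxialRecording-class] covering at least `k`
#'   subjects and both classes.
#' @param spec a [ClassifierSpec-class].
#' @param featureSet `"multiphase"` or `"conventional"`.
#' @param cfg a [WindowingConfig-class].
#' @param k number of folds (default 5).
#' @param seed integer root seed (folds, undersampling, model fits).
#' @param threshold score threshold for the confusion counts.
#' @return list with elements `pooled` ([MetricsReport-class]), `perFold`
#'   (list of [MetricsReport-class]), `scores` (data.frame of pooled test
#'   scores with fold, subject and label), `folds` ([FoldAssignment-class]),
#'   `templates` (per-fold [MotherWaveletTemplate-class] or `NULL`), and
#'   `missedFalls`.
#' @export
runCV <- function(recordings, spec = classifierSpec(),
                  featureSet = c("multiphase", "conventional"),
                  cfg = windowingConfig(), k = 5, seed = 1, threshold = 0.5) {
  featureSet <- match.arg(featureSet)
  col <- collectCFWs(recordings, cfg)
  cfws <- col$cfws
  if (!length(cfws)) stop("no candidate fall windows in the dataset")
  labels <- vapply(cfws, cfwLabel, character(1))
  subs <- vapply(cfws, subjectId, character(1))

  counts <- .subjectCounts(data.frame(subjectId = subs, label = labels))
  # subjects whose every fall was missed still need a fold
  for (s in setdiff(col$missedFallSubjects, counts$subjectId))
    counts <- rbind(counts, data.frame(
      subjectId = s, nFalls = 0L, nADLs = 0L))
  counts$nFalls <- counts$nFalls +
    vapply(counts$subjectId,
           function(s) sum(col$missedFallSubjects == s), integer(1))
  folds <- stratifyFolds(counts, k = k, seed = seed)
  cfwFold <- foldOf(folds)[subs]
  missedFold <- foldOf(folds)[col$missedFallSubjects]

  perFold <- vector("list", k)
  templates <- vector("list", k)
  pooledScores <- data.frame()
  for (f in seq_len(k)) {
    trainCfws <- cfws[cfwFold != f]
    testCfws <- cfws[cfwFold == f]
    trainFalls <- Filter(function(w) cfwLabel(w) == "fall", trainCfws)
    template <- NULL
    if (featureSet == "multiphase") {
      template <- buildMotherWavelet(trainFalls)
      templates[[f]] <- template
    }
    trainTab <- extractFeatures(trainCfws, featureSet, template)
    testTab <- extractFeatures(testCfws, featureSet, template)
    det <- trainDetector(spec, trainTab, seed = .deriveSeed(seed, f),
                         template = template)
    sc <- predictScores(det, testTab)
    nMissed <- sum(missedFold == f)
    # fold-level FA/h uses the test subjects' own monitored hours
    foldSubjects <- names(foldOf(folds))[foldOf(folds) == f]
    foldHours <- sum(col$adlHoursBySubject[
      names(col$adlHoursBySubject) %in% foldSubjects])
    perFold[[f]] <- computeMetrics(sc, testTab$label,
                                   monitoredHours = max(foldHours, 1e-12),
                                   threshold = threshold,
                                   nMissedFalls = nMissed)
    if (nrow(testTab))
      pooledScores <- rbind(pooledScores, data.frame(
        fold = f, subjectId = testTab$subjectId,
        recordingId = testTab$recordingId, label = testTab$label,
        score = sc))
  }
  pooled <- computeMetrics(pooledScores$score, pooledScores$label,
                           monitoredHours = col$monitoredHours,
                           threshold = threshold,
                           nMissedFalls = length(col$missedFallSubjects))
  list(pooled = pooled, perFold = perFold, scores = pooledScores,
       folds = folds, templates = templates,
       missedFalls = length(col$missedFallSubjects))
}

#' Evaluate the multi-threshold baseline on a dataset
#'
#' Applies [kangasDetect()] to every CFW of the dataset (the same candidate
#' set the learned classifiers are scored on) and reports pooled metrics. The
#' detector needs no training, so there is no cross-validation; the AUC is not
#' reported because the output is binary.
#'
#' @param recordings list of [TriaxialRecording-class].
#' @param kcfg a [KangasConfig-class].
#' @param cfg a [WindowingConfig-class].
#' @param threshold kept at 0.5 so the binary detections map to the common
#'   metric machinery.
#' @return list with `pooled` ([MetricsReport-class]) and `detections`
#'   (data.frame).
#' @export
runKangasBaseline <- function(recordings, kcfg = kangasConfig(),
                              cfg = windowingConfig(), threshold = 0.5) {
  col <- collectCFWs(recordings, cfg)
  det <- vapply(col$cfws, kangasDetect, logical(1), cfg = kcfg)
  labels <- vapply(col$cfws, cfwLabel, character(1))
  pooled <- computeMetrics(as.numeric(det), labels,
                           monitoredHours = col$monitoredHours,
                           threshold = threshold,
                           nMissedFalls = length(col$missedFallSubjects),
                           computeAUC = FALSE)
  list(pooled = pooled,
       detections = data.frame(
         recordingId = vapply(col$cfws, recordingId, character(1)),
         subjectId = vapply(col$cfws, subjectId, character(1)),
         peakSample = vapply(col$cfws, peakSample, integer(1)),
         label = labels, detected = det))
}
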