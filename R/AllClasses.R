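#' @import methods
NULL

#' TriaxialRecording: a continuous triaxial accelerometer stream
#'
#' Container for one continuous recording from a lower-back worn triaxial
#' accelerometer. Samples are stored per axis in units of g. Fall recordings
#' carry the annotated impact sample (IS), the sample index at which the body
#' hit the ground; ADL (activity of daily living) recordings do not.
#'
#' All sample indices in this package are 0-based: time `t` seconds
#' corresponds to sample `round(t * fs)`.
#'
#' @slot subjectId character, subject identifier.
#' @slot recordingId character, recording identifier (unique within a dataset).
#' @slot kind `"fall"` or `"adl"`.
#' @slot fs sampling frequency in Hz.
#' @slot ax,ay,az numeric vectors of per-sample acceleration in g.
#' @slot rangeG full scale of the sensor in g (typically 2 or 6).
#' @slot impactSample 0-based annotated impact sample; `NA` for ADL recordings.
#'
#' @seealso [triaxialRecording()], [readRecording()], [computeNorm()],
#'   [clipToRange()]
#' @export
setClass("TriaxialRecording",
  representation(
    subjectId = "character",
    recordingId = "character",
    kind = "character",
    fs = "numeric",
    ax = "numeric",
    ay = "numeric",
    az = "numeric",
    rangeG = "numeric",
    impactSample = "integer"
  )
)

setValidity("TriaxialRecording", function(object) {
  msg <- character()
  n <- length(object@ax)
  if (length(object@kind) != 1L || !object@kind %in% c("fall", "adl"))
    msg <- c(msg, "kind must be 'fall' or 'adl'")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a positive number")
  if (n < 1L) msg <- c(msg, "recording must contain at least one sample")
  if (length(object@ay) != n || length(object@az) != n)
    msg <- c(msg, "ax, ay, az must have equal length")
  if (anyNA(object@ax) || anyNA(object@ay) || anyNA(object@az) ||
      any(!is.finite(object@ax)) || any(!is.finite(object@ay)) ||
      any(!is.finite(object@az)))
    msg <- c(msg, "all samples must be finite")
  if (length(object@rangeG) != 1L || !is.finite(object@rangeG) ||
      object@rangeG <= 0)
    msg <- c(msg, "rangeG must be a positive number")
  if (identical(object@kind, "fall")) {
    if (length(object@impactSample) != 1L || is.na(object@impactSample))
      msg <- c(msg, "fall recordings require an impact sample")
    else if (object@impactSample < 0L || object@impactSample >= n)
      msg <- c(msg, "impactSample must satisfy 0 <= impactSample < length")
  }
  if (length(msg)) msg else TRUE
})

#' NormSignal: the acceleration norm of a recording
#'
#' Per-sample Euclidean norm of the three acceleration axes, in g. The norm is
#' invariant to sensor orientation (axis permutation and sign flips), which is
#' the property the multiphase feature set builds on.
#'
#' @slot values numeric vector of norm samples (all `>= 0`), in g.
#' @slot fs sampling frequency in Hz.
#' @slot recordingId identifier of the source recording.
#'
#' @seealso [computeNorm()]
#' @export
setClass("NormSignal",
  representation(values = "numeric", fs = "numeric", recordingId = "character")
)

setValidity("NormSignal", function(object) {
  msg <- character()
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "norm values must be finite and non-negative")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a positive number")
  if (length(msg)) msg else TRUE
})

#' WindowingConfig: geometry of the sliding-window peak search
#'
#' The stream is scanned with overlapping analysis windows of `windowS`
#' seconds advanced by `stepS` seconds. Each window devotes its second second
#' (local interval \[1 s, 2 s)) to a peak search on the acceleration norm; a
#' supra-threshold peak anchors a candidate fall window (CFW) of `cfwS`
#' seconds that starts `prePeakS` before the peak and is partitioned into
#' pre-peak, peak, post-peak and post-impact phases.
#'
#' @slot windowS analysis window length, seconds (default 27.5).
#' @slot stepS window step, seconds (default 1). `windowS = cfwS + stepS`.
#' @slot cfwS CFW length, seconds (default 26.5).
#' @slot prePeakS pre-peak phase length, seconds (default 1).
#' @slot postPeakS post-peak phase length, seconds (default 1).
#' @slot postImpactS post-impact phase length, seconds (default 24.5).
#' @slot peakThresholdG peak-search discard threshold in g (default 1.4):
#'   windows whose search-interval maximum is below it yield nothing.
#'
#' @seealso [windowingConfig()], [findCFWs()]
#' @export
setClass("WindowingConfig",
  representation(
    windowS = "numeric", stepS = "numeric", cfwS = "numeric",
    prePeakS = "numeric", postPeakS = "numeric", postImpactS = "numeric",
    peakThresholdG = "numeric"
  )
)

setValidity("WindowingConfig", function(object) {
  msg <- character()
  tol <- 1e-9
  if (abs(object@windowS - (object@cfwS + object@stepS)) > tol)
    msg <- c(msg, "windowS must equal cfwS + stepS")
  if (abs(object@cfwS -
          (object@prePeakS + object@postPeakS + object@postImpactS)) > tol)
    msg <- c(msg, "cfwS must equal prePeakS + postPeakS + postImpactS")
  if (object@peakThresholdG <= 0)
    msg <- c(msg, "peakThresholdG must be positive")
  if (any(c(object@windowS, object@stepS, object@cfwS, object@prePeakS,
            object@postPeakS, object@postImpactS) <= 0))
    msg <- c(msg, "all durations must be positive")
  if (length(msg)) msg else TRUE
})

#' CandidateFallWindow: a peak-anchored excerpt of a recording
#'
#' A CFW holds `cfwS * fs + 1` samples (2651 at the defaults) of the
#' acceleration norm and the matching triaxial samples, anchored so that the
#' norm peak sits exactly `prePeakS` (1 s) after the CFW start. Local 0-based
#' phase indices at the defaults: pre-peak 0-99, peak 100, post-peak 101-200,
#' post-impact 201-2650.
#'
#' @slot recordingId,subjectId provenance identifiers.
#' @slot label `"fall"` or `"adl"` (inherited from the source recording).
#' @slot peakSample 0-based absolute index of the anchoring norm peak in the
#'   source recording.
#' @slot fs sampling frequency in Hz.
#' @slot norm numeric vector of norm samples covering the CFW.
#' @slot ax,ay,az matching triaxial samples.
#' @slot thresholdG the peak-search threshold the CFW was emitted under.
#'
#' @seealso [findCFWs()], [cfwPhases()], [extractFeatures()]
#' @export
setClass("CandidateFallWindow",
  representation(
    recordingId = "character", subjectId = "character", label = "character",
    peakSample = "integer", fs = "numeric",
    norm = "numeric", ax = "numeric", ay = "numeric", az = "numeric",
    thresholdG = "numeric"
  )
)

setValidity("CandidateFallWindow", function(object) {
  msg <- character()
  n <- length(object@norm)
  if (!object@label %in% c("fall", "adl"))
    msg <- c(msg, "label must be 'fall' or 'adl'")
  if (length(object@ax) != n || length(object@ay) != n ||
      length(object@az) != n)
    msg <- c(msg, "norm and triaxial slots must have equal length")
  if (any(!is.finite(object@norm)) || any(object@norm < 0))
    msg <- c(msg, "norm values must be finite and non-negative")
  peakLocal <- as.integer(round(object@fs)) + 1L  # 1 s after CFW start, 1-based
  if (n < peakLocal) {
    msg <- c(msg, "CFW too short to contain its peak")
  } else if (object@norm[peakLocal] < object@thresholdG - 1e-12) {
    msg <- c(msg, "anchoring peak is below the emission threshold")
  }
  if (object@peakSample < 0L)
    msg <- c(msg, "peakSample must be non-negative")
  if (length(msg)) msg else TRUE
})

#' MotherWaveletTemplate: averaged impact-phase fall template
#'
#' The template is the pointwise mean of the 201-sample impact segments
#' (pre-peak + peak + post-peak) of the training-set fall CFWs, de-meaned and
#' scaled to unit energy. It acts as a single-scale matched filter: the
#' wavelet-similarity feature is the normalized correlation between this
#' template and a CFW's impact segment.
#'
#' @slot values numeric template, zero mean and unit sum of squares.
#' @slot nTrainingFalls number of fall CFWs averaged.
#'
#' @seealso [buildMotherWavelet()], [waveletSimilarity()]
#' @export
setClass("MotherWaveletTemplate",
  representation(values = "numeric", nTrainingFalls = "integer")
)

setValidity("MotherWaveletTemplate", function(object) {
  msg <- character()
  if (abs(mean(object@values)) > 1e-9)
    msg <- c(msg, "template must have zero mean")
  if (abs(sum(object@values^2) - 1) > 1e-9)
    msg <- c(msg, "template must have unit energy")
  if (object@nTrainingFalls < 1L)
    msg <- c(msg, "template must be built from at least one fall")
  if (length(msg)) msg else TRUE
})

#' KangasConfig: thresholds of the comparator multi-threshold detector
#'
#' Configuration of the classical three-stage threshold detector used as a
#' baseline: (1) free-fall check, acceleration below `freefallThresholdG`;
#' (2) impact check, a subsequent norm sample above `impactThresholdG`;
#' (3) lying-posture check, the low-pass filtered vertical axis averaged over
#' `postureWindowS` after the impact below `postureThresholdG` in magnitude.
#'
#' @slot freefallThresholdG free-fall threshold, g (default 0.75).
#' @slot impactThresholdG impact threshold, g (default 2).
#' @slot postureLowpassHz low-pass cutoff for the posture check, Hz
#'   (default 0.25; 2nd-order zero-phase Butterworth).
#' @slot postureWindowS averaging interval after the impact sample, seconds
#'   (default `c(1.6, 2)`).
#' @slot postureThresholdG lying threshold on the filtered vertical axis, g
#'   (default 0.5).
#' @slot verticalAxis `"x"`, `"y"`, `"z"`, or `"auto"` (estimate the gravity
#'   carrier from the pre-peak second of each CFW).
#' @slot freefallOnNorm if `TRUE` (default) the free-fall check tests the
#'   norm; if `FALSE`, the literal per-axis reading (all axes within the
#'   threshold in magnitude).
#'
#' @seealso [kangasConfig()], [kangasDetect()]
#' @export
setClass("KangasConfig",
  representation(
    freefallThresholdG = "numeric", impactThresholdG = "numeric",
    postureLowpassHz = "numeric", postureWindowS = "numeric",
    postureThresholdG = "numeric", verticalAxis = "character",
    freefallOnNorm = "logical"
  )
)

setValidity("KangasConfig", function(object) {
  msg <- character()
  if (!(object@freefallThresholdG > 0 &&
        object@freefallThresholdG < object@impactThresholdG))
    msg <- c(msg, "need 0 < freefallThresholdG < impactThresholdG")
  if (length(object@postureWindowS) != 2L ||
      diff(object@postureWindowS) <= 0 || any(object@postureWindowS < 0))
    msg <- c(msg, "postureWindowS must be an increasing non-negative pair")
  if (!object@verticalAxis %in% c("x", "y", "z", "auto"))
    msg <- c(msg, "verticalAxis must be x, y, z or auto")
  if (length(msg)) msg else TRUE
})

#' ClassifierSpec: classifier family and training hyperparameters
#'
#' @slot family one of `"naive_bayes"`, `"logistic_regression"`, `"knn"`,
#'   `"random_forest"`, `"svm_rbf"`.
#' @slot knnK neighbours for KNN (default 3).
#' @slot rfTrees trees for the random forest (default 20; regression mode so
#'   the ensemble mean is a score in \[0, 1\]).
#' @slot svmCGrid,svmGammaGrid RBF-SVM grid-search values (defaults
#'   `2^(-5:15)` and `2^(-15:3)`).
#' @slot standardize whether features are standardized with training-set
#'   means/SDs (default `TRUE` for KNN and SVM, `FALSE` otherwise).
#' @slot undersampleFraction fraction of majority-class (ADL) training rows
#'   retained (default 0.10).
#'
#' @seealso [classifierSpec()], [trainDetector()]
#' @export
setClass("ClassifierSpec",
  representation(
    family = "character", knnK = "integer", rfTrees = "integer",
    svmCGrid = "numeric", svmGammaGrid = "numeric",
    standardize = "logical", undersampleFraction = "numeric"
  )
)

setValidity("ClassifierSpec", function(object) {
  msg <- character()
  fams <- c("naive_bayes", "logistic_regression", "knn", "random_forest",
            "svm_rbf")
  if (length(object@family) != 1L || !object@family %in% fams)
    msg <- c(msg, paste("family must be one of:", paste(fams, collapse = ", ")))
  if (!length(object@svmCGrid) || !length(object@svmGammaGrid))
    msg <- c(msg, "SVM grids must be non-empty")
  if (!(object@undersampleFraction > 0 && object@undersampleFraction <= 1))
    msg <- c(msg, "undersampleFraction must be in (0, 1]")
  if (object@knnK < 1L) msg <- c(msg, "knnK must be >= 1")
  if (object@rfTrees < 1L) msg <- c(msg, "rfTrees must be >= 1")
  if (length(msg)) msg else TRUE
})

#' TrainedDetector: a fitted fall classifier with its preprocessing state
#'
#' Bundles the fitted model with everything needed to score new feature rows:
#' the feature set and column order, standardization means/SDs (derived from
#' training rows only), and the mother-wavelet template in force when the
#' multiphase features were extracted.
#'
#' @slot model the fitted model object (family-specific).
#' @slot spec the [ClassifierSpec-class] used.
#' @slot featureSet `"multiphase"` or `"conventional"`.
#' @slot featureNames feature column names, in training order.
#' @slot center,scale standardization parameters (length 0 when
#'   standardization is off).
#' @slot template the [MotherWaveletTemplate-class] (or `NULL` for
#'   conventional features).
#' @slot svmC,svmGamma selected SVM hyperparameters (`NA` for other families).
#' @slot platt coefficients of the Platt score calibration for the SVM
#'   (length 0 otherwise).
#'
#' @seealso [trainDetector()], [predictScores()]
#' @export
setClass("TrainedDetector",
  representation(
    model = "ANY", spec = "ClassifierSpec", featureSet = "character",
    featureNames = "character", center = "numeric", scale = "numeric",
    template = "ANY", svmC = "numeric", svmGamma = "numeric",
    platt = "numeric"
  )
)

#' FoldAssignment: subject-level stratified cross-validation folds
#'
#' Maps every subject to exactly one fold so that all of a subject's windows
#' (falls and ADLs) stay together. Subjects are stratified into
#' low/high-ADL-count and, for fallers without ADLs, low/high-fall-count
#' groups; each stratum is spread round-robin over the folds so per-stratum
#' fold counts differ by at most one.
#'
#' @slot folds named integer vector: subject id -> fold in `1..k`.
#' @slot k number of folds.
#' @slot strata named character vector: subject id -> stratum label
#'   (`adl_low`, `adl_high`, `fall_low`, `fall_high`).
#' @slot seed seed that produced the within-stratum shuffle.
#'
#' @seealso [stratifyFolds()], [runCV()]
#' @export
setClass("FoldAssignment",
  representation(folds = "integer", k = "integer", strata = "character",
                 seed = "integer")
)

setValidity("FoldAssignment", function(object) {
  msg <- character()
  subj <- names(object@folds)
  if (is.null(subj) || anyDuplicated(subj))
    msg <- c(msg, "every subject must appear in exactly one fold")
  if (any(object@folds < 1L) || any(object@folds > object@k))
    msg <- c(msg, "fold indices must lie in 1..k")
  if (length(object@strata) != length(object@folds) ||
      !setequal(names(object@strata), subj))
    msg <- c(msg, "strata must label exactly the assigned subjects")
  else {
    for (s in unique(object@strata)) {
      cnt <- tabulate(object@folds[names(object@strata)[object@strata == s]],
                      nbins = object@k)
      if (diff(range(cnt)) > 1L)
        msg <- c(msg, sprintf("stratum '%s' is unbalanced across folds", s))
    }
  }
  if (length(msg)) msg else TRUE
})

#' MetricsReport: confusion counts and detection metrics
#'
#' Ratios with an undefined denominator (for example sensitivity with no
#' positives) are reported as `NA`, never as 0. False alarms per hour is
#' `FP / monitoredHours`, the practical usability figure for continuous
#' monitoring.
#'
#' @slot tp,fp,tn,fn confusion counts at the score threshold.
#' @slot sensitivity,specificity,ppv,fMeasure proportions in \[0, 1\].
#' @slot faPerHour false alarms per monitored hour.
#' @slot auc area under the ROC curve (`NA` when scores are binary-only or a
#'   class is absent).
#' @slot monitoredHours total ADL hours the false alarms are scaled by.
#' @slot threshold score threshold used for the confusion counts.
#'
#' @seealso [computeMetrics()], [rocAUC()]
#' @export
setClass("MetricsReport",
  representation(
    tp = "integer", fp = "integer", tn = "integer", fn = "integer",
    sensitivity = "numeric", specificity = "numeric", ppv = "numeric",
    fMeasure = "numeric", faPerHour = "numeric", auc = "numeric",
    monitoredHours = "numeric", threshold = "numeric"
  )
)

setValidity("MetricsReport", function(object) {
  msg <- character()
  if (any(c(object@tp, object@fp, object@tn, object@fn) < 0L))
    msg <- c(msg, "confusion counts must be non-negative")
  if (object@monitoredHours < 0)
    msg <- c(msg, "monitoredHours must be non-negative")
  if (length(msg)) msg else TRUE
})
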