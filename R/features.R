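# Local 1-based index helpers for the fixed phase geometry (1 s pre-peak,
# peak, 1 s post-peak). fs1 = samples per second.
.fs1 <- function(cfw) as.integer(round(cfw@fs))

.impactIdx <- function(cfw) seq_len(2L * .fs1(cfw) + 1L)

#' Lower peak value (LPV)
#'
#' Minimum of the acceleration norm over the pre-peak (descent) phase, in g.
#' A genuine fall shows a free-fall dip well below 1 g here.
#'
#' @param cfw a [CandidateFallWindow-class].
#' @return minimum pre-peak norm, in g.
#' @export
lowerPeakValue <- function(cfw) {
  min(cfw@norm[seq_len(.fs1(cfw))])
}

#' Upper peak value (UPV)
#'
#' The anchoring norm peak, in g: the value of the signal 1 s after the CFW
#' start. By construction it equals the maximum of the search interval that
#' emitted the CFW, hence is at least the peak-search threshold.
#'
#' @param cfw a [CandidateFallWindow-class].
#' @return peak norm value, in g.
#' @export
upperPeakValue <- function(cfw) {
  cfw@norm[.fs1(cfw) + 1L]
}

#' Build the mother-wavelet template from training falls
#'
#' The template is the pointwise mean of the impact segments (pre-peak + peak
#' + post-peak, 201 samples at 100 Hz) of the training-set fall CFWs,
#' de-meaned and scaled to unit energy so that the similarity feature is a
#' normalized correlation. It must be built from training data only; the
#' cross-validation driver rebuilds it per fold.
#'
#' @param trainingFallCFWs non-empty list of fall [CandidateFallWindow-class].
#' @return a [MotherWaveletTemplate-class].
#' @export
buildMotherWavelet <- function(trainingFallCFWs) {
  if (!length(trainingFallCFWs))
    stop("cannot build a mother wavelet from zero training falls")
  segs <- vapply(trainingFallCFWs,
                 function(w) w@norm[.impactIdx(w)],
                 numeric(2L * .fs1(trainingFallCFWs[[1L]]) + 1L))
  avg <- rowMeans(segs)
  avg <- avg - mean(avg)
  energy <- sum(avg^2)
  if (energy == 0)
    stop("training falls have a constant average impact segment; ",
         "template undefined")
  new("MotherWaveletTemplate", values = avg / sqrt(energy),
      nTrainingFalls = length(trainingFallCFWs))
}

setMethod("show", "MotherWaveletTemplate", function(object) {
  cat(sprintf(
    "MotherWaveletTemplate: %d samples, built from %d training fall(s)\n",
    length(object@values), object@nTrainingFalls))
})

#' Wavelet similarity of a CFW to the mother-wavelet template
#'
#' Normalized zero-lag correlation (a single-scale matched filter) between the
#' template and the de-meaned, energy-normalized impact segment of the CFW.
#' Lies in \[-1, 1\]; a zero-variance segment scores 0 by definition.
#'
#' @param cfw a [CandidateFallWindow-class].
#' @param template a [MotherWaveletTemplate-class] built on training data
#'   only.
#' @return similarity coefficient in \[-1, 1\].
#' @export
waveletSimilarity <- function(cfw, template) {
  stopifnot(is(template, "MotherWaveletTemplate"))
  seg <- cfw@norm[.impactIdx(cfw)]
  if (length(seg) != length(template@values))
    stop("CFW impact segment and template lengths differ")
  seg <- seg - mean(seg)
  energy <- sum(seg^2)
  if (energy == 0) return(0)
  sum(seg / sqrt(energy) * template@values)
}

#' Periodicity after impact
#'
#' Maximum lagged autocorrelation of the norm over a 2-s segment starting
#' 0.5 s after the peak sample. Walking or running right after the candidate
#' impact produces a strong periodic component at the step period; a genuine
#' fall (resting or struggling) does not. Computed as the largest per-lag
#' Pearson correlation between the segment and its lagged copy over lags of
#' 0.2-1.0 s, clamped to \[0, 1\]; a zero-variance segment scores 0.
#'
#' @param cfw a [CandidateFallWindow-class].
#' @return periodicity score in \[0, 1\].
#' @export
periodicityAfterImpact <- function(cfw) {
  fs1 <- .fs1(cfw)
  start <- fs1 + fs1 %/% 2L    # 0.5 s after the peak (0-based local index)
  x <- cfw@norm[(start + 1L):(start + 2L * fs1)]
  n <- length(x)
  if (stats::sd(x) == 0) return(0)
  lags <- seq.int(fs1 %/% 5L, fs1)  # 0.2 s .. 1.0 s
  best <- max(vapply(lags, function(k) {
    a <- x[seq_len(n - k)]
    b <- x[(k + 1L):n]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }, numeric(1)))
  min(max(best, 0), 1)
}

#' Standard deviation after impact
#'
#' Sample standard deviation (denominator n-1) of the norm over the
#' post-impact phase, in g. Lying still after a fall yields values near the
#' sensor noise floor; resumed activity yields much larger values.
#'
#' @param cfw a [CandidateFallWindow-class].
#' @return post-impact SD, in g.
#' @export
postImpactSD <- function(cfw) {
  idx <- cfwPhases(cfw)$postImpact + 1L
  stats::sd(cfw@norm[idx])
}

#' Conventional features of a CFW
#'
#' The 16 statistics commonly used in fall-detection studies: max, min, mean
#' and sample SD of each of ax, ay, az and the norm, over the full CFW. Unlike
#' the multiphase set these depend on sensor orientation.
#'
#' @param cfw a [CandidateFallWindow-class].
#' @return named numeric vector of 16 features.
#' @export
conventionalFeatures <- function(cfw) {
  chans <- list(ax = cfw@ax, ay = cfw@ay, az = cfw@az, norm = cfw@norm)
  out <- unlist(lapply(chans, function(v)
    c(max = max(v), min = min(v), mean = mean(v), sd = stats::sd(v))))
  names(out) <- sub("\\.", "_", names(out))
  out
}

#' Multiphase features of a CFW
#'
#' The five features of the multiphase fall model: lower peak value (descent
#' dip), upper peak value (impact magnitude), wavelet similarity to the
#' training-fall template (impact shape), periodicity after impact (absence of
#' walking), and post-impact SD (rest vs. activity). All are computed from the
#' orientation-invariant acceleration norm.
#'
#' @param cfw a [CandidateFallWindow-class].
#' @param template a [MotherWaveletTemplate-class].
#' @return named numeric vector of 5 features.
#' @export
multiphaseFeatures <- function(cfw, template) {
  c(LPV = lowerPeakValue(cfw),
    UPV = upperPeakValue(cfw),
    wavelet_similarity = waveletSimilarity(cfw, template),
    periodicity = periodicityAfterImpact(cfw),
    post_impact_sd = postImpactSD(cfw))
}

#' Names of the feature columns of a feature set
#' @param featureSet `"multiphase"` or `"conventional"`.
#' @return character vector of feature column names.
#' @export
featureNames <- function(featureSet = c("multiphase", "conventional")) {
  featureSet <- match.arg(featureSet)
  if (featureSet == "multiphase")
    c("LPV", "UPV", "wavelet_similarity", "periodicity", "post_impact_sd")
  else
    as.vector(outer(c("max", "min", "mean", "sd"),
                    c("ax", "ay", "az", "norm"),
                    function(s, ch) paste(ch, s, sep = "_")))
}

#' Extract a feature table from CFWs
#'
#' One row per CFW with provenance columns (`subjectId`, `recordingId`,
#' `peakSample`, `label`) followed by the named feature columns. Extraction is
#' pure: identical CFWs and template give identical rows.
#'
#' @param cfws list of [CandidateFallWindow-class].
#' @param featureSet `"multiphase"` or `"conventional"`.
#' @param template a [MotherWaveletTemplate-class]; required iff
#'   `featureSet = "multiphase"`.
#' @return a `data.frame` feature table (zero rows for empty input), with
#'   attribute `featureSet`.
#' @export
extractFeatures <- function(cfws, featureSet = c("multiphase", "conventional"),
                            template = NULL) {
  featureSet <- match.arg(featureSet)
  if (featureSet == "multiphase" && is.null(template))
    stop("multiphase features require a mother-wavelet template")
  fn <- featureNames(featureSet)
  meta <- data.frame(subjectId = character(0), recordingId = character(0),
                     peakSample = integer(0), label = character(0))
  if (!length(cfws)) {
    out <- cbind(meta, as.data.frame(matrix(numeric(0), 0, length(fn),
                                            dimnames = list(NULL, fn))))
    attr(out, "featureSet") <- featureSet
    return(out)
  }
  feats <- t(vapply(cfws, function(w) {
    if (featureSet == "multiphase") multiphaseFeatures(w, template)
    else conventionalFeatures(w)
  }, stats::setNames(numeric(length(fn)), fn)))
  out <- data.frame(
    subjectId = vapply(cfws, subjectId, character(1)),
    recordingId = vapply(cfws, recordingId, character(1)),
    peakSample = vapply(cfws, peakSample, integer(1)),
    label = vapply(cfws, cfwLabel, character(1)),
    feats, check.names = FALSE)
  stopifnot(!anyNA(out))
  attr(out, "featureSet") <- featureSet
  rownames(out) <- NULL
  out
}

#' Feature columns of a feature table
#' @param table a feature table from [extractFeatures()].
#' @return character vector of its feature column names.
#' @export
featureColumns <- function(table) {
  setdiff(names(table), c("subjectId", "recordingId", "peakSample", "label"))
}
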