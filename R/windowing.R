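#' Construct a WindowingConfig
#'
#' Defaults encode the published geometry: 27.5-s windows stepped by 1 s
#' (96.4% overlap), a 26.5-s CFW with 1-s pre-peak, 1-s post-peak and 24.5-s
#' post-impact phases, and a 1.4 g peak-search discard threshold.
#'
#' @param windowS,stepS,cfwS,prePeakS,postPeakS,postImpactS durations in
#'   seconds; see [WindowingConfig-class].
#' @param peakThresholdG peak-search threshold in g.
#' @return a validated [WindowingConfig-class].
#' @export
windowingConfig <- function(windowS = 27.5, stepS = 1, cfwS = 26.5,
                            prePeakS = 1, postPeakS = 1, postImpactS = 24.5,
                            peakThresholdG = 1.4) {
  new("WindowingConfig", windowS = windowS, stepS = stepS, cfwS = cfwS,
      prePeakS = prePeakS, postPeakS = postPeakS, postImpactS = postImpactS,
      peakThresholdG = peakThresholdG)
}

setMethod("show", "WindowingConfig", function(object) {
  cat(sprintf(
    "WindowingConfig: %g s windows, %g s step, %g s CFW (%g+%g+%g s phases), peak threshold %g g\n",
    object@windowS, object@stepS, object@cfwS, object@prePeakS,
    object@postPeakS, object@postImpactS, object@peakThresholdG))
})

#' Sliding-window starts for a recording
#'
#' 0-based start samples of the full analysis windows laid over a recording of
#' `n` samples: `0, stepS*fs, 2*stepS*fs, ...`; trailing data that cannot fill
#' a whole window is ignored.
#'
#' @param n recording length in samples.
#' @param cfg a [WindowingConfig-class].
#' @param fs sampling frequency in Hz.
#' @return integer vector of 0-based window starts (length 0 when the
#'   recording is shorter than one window), with attributes `windowSamples`
#'   and `stepSamples`.
#' @export
slidingWindowStarts <- function(n, cfg = windowingConfig(), fs = 100) {
  win_n <- as.integer(round(cfg@windowS * fs))
  step_n <- as.integer(round(cfg@stepS * fs))
  starts <- if (n < win_n) integer(0)
            else as.integer(seq.int(0L, n - win_n, by = step_n))
  structure(starts, windowSamples = win_n, stepSamples = step_n)
}

#' Find candidate fall windows in a recording
#'
#' Lays overlapping analysis windows over the acceleration norm (see
#' [slidingWindowStarts()]); within each window the second second (local
#' interval \[1 s, 2 s)) is the peak-search interval. The window's peak is the
#' maximum of the norm over that interval. If the peak is below
#' `peakThresholdG` the window is discarded as minimal movement; otherwise one
#' CFW is emitted, anchored at the peak's argmax (the earliest sample on exact
#' amplitude ties). Because consecutive search intervals tile the timeline,
#' every sample from 1 s onward (within coverage) is searched exactly once.
#'
#' @param norm the [NormSignal-class] of `rec`.
#' @param rec the source [TriaxialRecording-class] (supplies the matching
#'   triaxial samples and the label).
#' @param cfg a [WindowingConfig-class].
#' @return a list of [CandidateFallWindow-class] objects (possibly empty). A
#'   recording shorter than one window yields an empty list with a warning.
#' @examples
#' rec <- simulateFallRecording(synthConfig(), "s1", seed = 7)
#' cfws <- findCFWs(computeNorm(clipToRange(rec)), rec)
#' length(cfws)
#' @export
findCFWs <- function(norm, rec, cfg = windowingConfig()) {
  stopifnot(is(norm, "NormSignal"), is(rec, "TriaxialRecording"))
  if (!isTRUE(all.equal(norm@fs, rec@fs)))
    stop("norm and recording sampling rates differ")
  v <- norm@values
  n <- length(v)
  if (n != nSamples(rec))
    stop("norm and recording lengths differ")
  fs <- rec@fs
  starts <- slidingWindowStarts(n, cfg, fs)
  if (!length(starts)) {
    warning("recording '", rec@recordingId,
            "' is shorter than one analysis window; no CFWs extracted")
    return(list())
  }
  step_n <- attr(starts, "stepSamples")
  pre_n <- as.integer(round(cfg@prePeakS * fs))
  after_n <- as.integer(round((cfg@postPeakS + cfg@postImpactS) * fs))
  out <- vector("list", length(starts))
  k <- 0L
  for (s in starts) {
    search <- (s + step_n + 1L):(s + 2L * step_n)  # 1-based indices
    seg <- v[search]
    peak <- max(seg)
    if (peak < cfg@peakThresholdG) next
    p <- s + step_n + which.max(seg) - 1L          # 0-based absolute index
    span <- (p - pre_n + 1L):(p + after_n + 1L)    # 1-based CFW coverage
    k <- k + 1L
    out[[k]] <- new("CandidateFallWindow",
                    recordingId = rec@recordingId, subjectId = rec@subjectId,
                    label = rec@kind, peakSample = as.integer(p), fs = fs,
                    norm = v[span], ax = rec@ax[span], ay = rec@ay[span],
                    az = rec@az[span], thresholdG = cfg@peakThresholdG)
  }
  out[seq_len(k)]
}

#' Select the fall CFW nearest the annotated impact
#'
#' A fall recording can yield several CFWs (multiple impacts, post-fall
#' activity). For sensitivity scoring a single representative window is kept:
#' the one whose anchoring peak is nearest the annotated impact sample, with
#' the earlier peak winning distance ties.
#'
#' @param cfws list of [CandidateFallWindow-class] from one fall recording.
#' @param impactSample 0-based annotated impact sample.
#' @return one [CandidateFallWindow-class], or `NULL` when `cfws` is empty
#'   (the fall then counts as a missed detection downstream).
#' @export
selectFallCFW <- function(cfws, impactSample) {
  if (!length(cfws)) return(NULL)
  peaks <- vapply(cfws, peakSample, integer(1))
  d <- abs(peaks - as.integer(impactSample))
  cfws[[order(d, peaks)[1L]]]
}

#' Retain all ADL CFWs
#'
#' Every CFW found in an ADL recording is a potential false alarm, so all are
#' retained for specificity scoring. Labels are set to `"adl"`.
#'
#' @param cfws list of [CandidateFallWindow-class].
#' @return the same list with labels set to `"adl"`.
#' @export
selectADLCFWs <- function(cfws) {
  lapply(cfws, function(w) { w@label <- "adl"; w })
}

#' @rdname CandidateFallWindow-class
#' @export
setMethod("peakSample", "CandidateFallWindow", function(x) x@peakSample)
#' @rdname CandidateFallWindow-class
#' @export
setMethod("cfwLabel", "CandidateFallWindow", function(x) x@label)
#' @rdname CandidateFallWindow-class
#' @export
setMethod("subjectId", "CandidateFallWindow", function(x) x@subjectId)
#' @rdname CandidateFallWindow-class
#' @export
setMethod("recordingId", "CandidateFallWindow", function(x) x@recordingId)
#' @rdname CandidateFallWindow-class
#' @export
setMethod("normValues", "CandidateFallWindow", function(x) x@norm)
#' @rdname CandidateFallWindow-class
#' @export
setMethod("samplingRate", "CandidateFallWindow", function(x) x@fs)
#' @rdname CandidateFallWindow-class
#' @export
setMethod("axisMatrix", "CandidateFallWindow", function(x)
  cbind(ax = x@ax, ay = x@ay, az = x@az))

setMethod("show", "CandidateFallWindow", function(object) {
  cat(sprintf(
    "CandidateFallWindow (%s) of '%s', subject %s: peak %.3f g at sample %d (t = %.2f s), %d samples\n",
    object@label, object@recordingId, object@subjectId,
    object@norm[as.integer(round(object@fs)) + 1L], object@peakSample,
    object@peakSample / object@fs, length(object@norm)))
})

#' Phase index map of a CFW
#'
#' Local 0-based sample indices of the multiphase decomposition: the 1-s
#' pre-peak (descent) phase, the peak sample, the 1-s post-peak phase and the
#' remaining post-impact phase. At the defaults (100 Hz, 26.5-s CFW):
#' pre-peak 0-99, peak 100, post-peak 101-200, post-impact 201-2650.
#'
#' @param cfw a [CandidateFallWindow-class].
#' @return named list of integer index vectors
#'   (`prePeak`, `peak`, `postPeak`, `postImpact`).
#' @export
cfwPhases <- function(cfw) {
  fs1 <- as.integer(round(cfw@fs))
  n <- length(cfw@norm)
  list(prePeak = 0:(fs1 - 1L), peak = fs1,
       postPeak = (fs1 + 1L):(2L * fs1),
       postImpact = (2L * fs1 + 1L):(n - 1L))
}

#' Time spans of a CFW and its phases
#'
#' Durations in seconds, measured on the emitted samples: the CFW span is the
#' time between its first and last covered instants; each phase duration is
#' the time the phase occupies after its predecessor's last sample. At the
#' defaults these are 26.5 s total with phases 1 + 0.01 + 1 + 24.5 s
#' (the peak is a single sample).
#'
#' @param cfw a [CandidateFallWindow-class].
#' @return named numeric vector `span`, `prePeak`, `postPeak`, `postImpact`,
#'   in seconds.
#' @export
cfwDurations <- function(cfw) {
  ph <- cfwPhases(cfw)
  fs <- cfw@fs
  c(span = (length(cfw@norm) - 1L) / fs,
    prePeak = length(ph$prePeak) / fs,
    postPeak = length(ph$postPeak) / fs,
    postImpact = length(ph$postImpact) / fs)
}
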