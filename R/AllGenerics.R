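#' @rdname TriaxialRecording-class
#' @param object,x a package object.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname TriaxialRecording-class
#' @export
setGeneric("recordingId", function(x) standardGeneric("recordingId"))

#' @rdname TriaxialRecording-class
#' @export
setGeneric("recordingKind", function(x) standardGeneric("recordingKind"))

#' @rdname TriaxialRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname TriaxialRecording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname TriaxialRecording-class
#' @export
setGeneric("impactSample", function(x) standardGeneric("impactSample"))

#' @rdname TriaxialRecording-class
#' @export
setGeneric("axisMatrix", function(x) standardGeneric("axisMatrix"))

#' @rdname NormSignal-class
#' @param x a package object.
#' @export
setGeneric("normValues", function(x) standardGeneric("normValues"))

#' @rdname CandidateFallWindow-class
#' @param x a `CandidateFallWindow`.
#' @export
setGeneric("peakSample", function(x) standardGeneric("peakSample"))

#' @rdname CandidateFallWindow-class
#' @export
setGeneric("cfwLabel", function(x) standardGeneric("cfwLabel"))

#' Clip a recording's axes to a symmetric dynamic range
#'
#' Replaces every axis sample `s` by `min(max(s, -limit), limit)`, emulating
#' the saturation of a sensor with full scale `±limit` g. Applied only when
#' the recording's stated range exceeds `limit`; used to normalize wider-range
#' (e.g. ±6 g) fall recordings into the ±2 g range of the remaining data.
#' Clipping acts on the axes before any norm computation, so the norm of a
#' clipped recording may still exceed `limit`.
#'
#' @param rec a [TriaxialRecording-class].
#' @param limit positive full scale in g (default 2).
#' @return the clipped [TriaxialRecording-class] with `rangeG` set to `limit`.
#' @examples
#' rec <- triaxialRecording("s1", "r1", "adl", ax = c(0, 3.2), ay = c(0, -2.5),
#'                          az = c(1, 1), rangeG = 6)
#' axisMatrix(clipToRange(rec, 2))
#' @export
setGeneric("clipToRange", function(rec, limit = 2) standardGeneric("clipToRange"))

#' Compute the acceleration norm of a recording
#'
#' The per-sample Euclidean norm `sqrt(ax^2 + ay^2 + az^2)` in g. The norm is
#' exactly invariant under axis permutations and sign flips, making it the
#' orientation-independent carrier for the multiphase features.
#'
#' @param rec a [TriaxialRecording-class].
#' @return a [NormSignal-class] of the same length.
#' @examples
#' rec <- triaxialRecording("s1", "r1", "adl", ax = c(0, 0.3), ay = c(0, 0.4),
#'                          az = c(1, 0))
#' normValues(computeNorm(rec))  # 1.0, 0.5
#' @export
setGeneric("computeNorm", function(rec) standardGeneric("computeNorm"))
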