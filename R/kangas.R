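#' Construct a KangasConfig
#'
#' Defaults encode the published multi-threshold detector: free fall below
#' 0.75 g, impact above 2 g, and a lying-posture check on the vertical axis
#' low-pass filtered at 0.25 Hz, averaged 1.6-2 s after the impact, below
#' 0.5 g.
#'
#' @param freefallThresholdG,impactThresholdG,postureLowpassHz,postureWindowS,postureThresholdG,verticalAxis,freefallOnNorm
#'   see [KangasConfig-class].
#' @return a validated [KangasConfig-class].
#' @export
kangasConfig <- function(freefallThresholdG = 0.75, impactThresholdG = 2,
                         postureLowpassHz = 0.25, postureWindowS = c(1.6, 2),
                         postureThresholdG = 0.5, verticalAxis = "auto",
                         freefallOnNorm = TRUE) {
  new("KangasConfig", freefallThresholdG = freefallThresholdG,
      impactThresholdG = impactThresholdG, postureLowpassHz = postureLowpassHz,
      postureWindowS = as.numeric(postureWindowS),
      postureThresholdG = postureThresholdG,
      verticalAxis = verticalAxis, freefallOnNorm = freefallOnNorm)
}

# median |axis value| closest to 1 g; ties resolved x < y < z
.gravityAxis <- function(ax, ay, az) {
  dev <- abs(c(x = stats::median(abs(ax)), y = stats::median(abs(ay)),
               z = stats::median(abs(az))) - 1)
  names(dev)[which.min(dev)]  # which.min takes the first on ties
}

#' Detect the vertical (gravity-carrying) axis of a recording
#'
#' The axis whose median absolute value is closest to 1 g over the whole
#' stream; for a mostly upright wearer this is the axis aligned with gravity.
#' Ties are resolved by the fixed priority x < y < z.
#'
#' @param rec a [TriaxialRecording-class] of at least 10 s.
#' @return `"x"`, `"y"` or `"z"`.
#' @export
detectVerticalAxis <- function(rec) {
  stopifnot(is(rec, "TriaxialRecording"))
  if (nSamples(rec) < 10 * rec@fs)
    stop("vertical-axis detection requires at least 10 s of signal")
  .gravityAxis(rec@ax, rec@ay, rec@az)
}

#' Multi-threshold (Kangas-style) fall detection on a CFW
#'
#' The comparator detector, confined to the CFW so that it is scored on the
#' same candidate set as the learned classifiers. Fires iff
#' \enumerate{
#'   \item free fall: some pre-peak sample of the norm is below
#'     `freefallThresholdG` (or, with `freefallOnNorm = FALSE`, all three axes
#'     are simultaneously below it in magnitude);
#'   \item impact: a later norm sample within the impact phase exceeds
#'     `impactThresholdG`; the first such sample is taken as the impact;
#'   \item lying posture: the vertical-axis signal, low-pass filtered with a
#'     zero-phase 2nd-order Butterworth at `postureLowpassHz`, averaged over
#'     `postureWindowS` after the impact sample, is below `postureThresholdG`
#'     in magnitude.
#' }
#' With `verticalAxis = "auto"` the vertical axis is estimated from the CFW's
#' pre-peak second (the wearer is still upright before a genuine fall), using
#' the same median rule as [detectVerticalAxis()].
#'
#' @param cfw a [CandidateFallWindow-class].
#' @param cfg a [KangasConfig-class].
#' @return `TRUE` if a fall is detected.
#' @export
kangasDetect <- function(cfw, cfg = kangasConfig()) {
  stopifnot(is(cfw, "CandidateFallWindow"), is(cfg, "KangasConfig"))
  fs1 <- as.integer(round(cfw@fs))
  pre <- seq_len(fs1)
  ff <- if (cfg@freefallOnNorm) {
    cfw@norm[pre] < cfg@freefallThresholdG
  } else {
    abs(cfw@ax[pre]) < cfg@freefallThresholdG &
      abs(cfw@ay[pre]) < cfg@freefallThresholdG &
      abs(cfw@az[pre]) < cfg@freefallThresholdG
  }
  if (!any(ff)) return(FALSE)
  ffIdx <- which(ff)[1L]

  impactPhase <- seq_len(2L * fs1 + 1L)
  cand <- impactPhase[impactPhase > ffIdx &
                        cfw@norm[impactPhase] > cfg@impactThresholdG]
  if (!length(cand)) return(FALSE)
  impIdx <- cand[1L]

  axis <- cfg@verticalAxis
  if (axis == "auto")
    axis <- .gravityAxis(cfw@ax[pre], cfw@ay[pre], cfw@az[pre])
  vert <- slot(cfw, paste0("a", axis))

  bf <- signal::butter(2, cfg@postureLowpassHz / (cfw@fs / 2), type = "low")
  filt <- signal::filtfilt(bf, vert)

  win <- impIdx + as.integer(round(cfg@postureWindowS[1] * cfw@fs)):
                  as.integer(round(cfg@postureWindowS[2] * cfw@fs))
  win <- win[win <= length(filt)]
  if (!length(win)) return(FALSE)
  abs(mean(filt[win])) < cfg@postureThresholdG
}
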