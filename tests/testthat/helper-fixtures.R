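# Programmatic fixtures shared across test files.

# A constant-gravity recording (1 g on az) with optional norm impulses:
# `impulses` is a data.frame(sample [0-based], value) added on ax so that the
# norm at the impulse equals sqrt(1 + value^2 - 1) -> we instead place the
# impulse on az directly for exact norm control.
impulseRecording <- function(nSeconds = 60, impulses = NULL, fs = 100,
                             kind = "adl", impactSample = NA,
                             subjectId = "s1", recordingId = "r1") {
  n <- nSeconds * fs
  az <- rep(1, n)
  if (!is.null(impulses))
    az[impulses$sample + 1L] <- impulses$value
  triaxialRecording(subjectId, recordingId, kind,
                    ax = rep(0, n), ay = rep(0, n), az = az, fs = fs,
                    impactSample = impactSample)
}

# Build a CandidateFallWindow directly from per-phase norm pieces (and
# optionally explicit axes). Default geometry: 100 Hz, 2651 samples.
makeCFW <- function(prePeak = rep(1, 100), peak = 2.5,
                    postPeak = rep(1, 100), postImpact = rep(1, 2450),
                    ax = NULL, ay = NULL, az = NULL,
                    label = "adl", subjectId = "s1", recordingId = "r1",
                    peakSample = 1000L, fs = 100) {
  nrm <- c(prePeak, peak, postPeak, postImpact)
  if (is.null(ax)) ax <- rep(0, length(nrm))
  if (is.null(ay)) ay <- rep(0, length(nrm))
  if (is.null(az)) az <- nrm  # consistent: norm of (0, 0, az) = |az|
  new("CandidateFallWindow", recordingId = recordingId,
      subjectId = subjectId, label = label,
      peakSample = as.integer(peakSample), fs = fs, norm = nrm,
      ax = ax, ay = ay, az = az, thresholdG = 0)
}

# CFW built from explicit axes; norm derived.
makeCFWFromAxes <- function(ax, ay, az, label = "adl", peakSample = 1000L,
                            fs = 100) {
  rec <- triaxialRecording("s1", "r1", "adl", ax = ax, ay = ay, az = az)
  new("CandidateFallWindow", recordingId = "r1", subjectId = "s1",
      label = label, peakSample = as.integer(peakSample), fs = fs,
      norm = normValues(computeNorm(rec)), ax = ax, ay = ay, az = az,
      thresholdG = 0)
}

# One shared small synthetic dataset, generated once per test run.
sharedDataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- simulateDataset(synthConfig())
    ds
  }
})

# A tiny linearly separable two-subject-per-fold feature table.
toyFeatureTable <- function(nPerClass = 12, nSubjects = 6, sep = 4,
                            seed = 42, featureSet = "multiphase") {
  fn <- featureNames(featureSet)
  withr::with_seed(seed, {
    lab <- rep(c("fall", "adl"), each = nPerClass)
    x <- matrix(rnorm(2 * nPerClass * length(fn), sd = 0.3),
                ncol = length(fn), dimnames = list(NULL, fn))
    x[lab == "fall", 1] <- x[lab == "fall", 1] + sep
    tab <- data.frame(
      subjectId = rep_len(sprintf("T%02d", seq_len(nSubjects)),
                          2 * nPerClass),
      recordingId = sprintf("rec%03d", seq_len(2 * nPerClass)),
      peakSample = seq_len(2 * nPerClass) * 100L,
      label = lab, x, check.names = FALSE)
    attr(tab, "featureSet") <- featureSet
    tab
  })
}
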