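# Independent brute-force oracles, kept deliberately simple and separate from
# the package's implementation paths.

# Peak-binning oracle for the windowing procedure: partition the timeline
# into consecutive 1-s search bins starting at t = 1 s; a bin whose window
# fits entirely in the recording emits one CFW at the argmax of the bin when
# that maximum reaches the threshold. Indices are 0-based like the package's.
oracleCFWPeaks <- function(v, threshold = 1.4, fs = 100) {
  n <- length(v)
  win <- 27.5 * fs
  step <- 1 * fs
  peaks <- integer(0)
  w <- 0L
  repeat {
    start <- w * step
    if (start + win > n) break
    bin <- (start + step + 1):(start + 2 * step)  # 1-based
    m <- max(v[bin])
    if (m >= threshold) {
      p <- bin[which.max(v[bin])] - 1L            # 0-based
      peaks <- c(peaks, p)
    }
    w <- w + 1L
  }
  peaks
}

# Pairwise Mann-Whitney concordance (ties count one half).
oracleAUC <- function(scores, labels) {
  pos <- which(labels == "fall" | labels == TRUE)
  neg <- which(!(labels == "fall" | labels == TRUE))
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}
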