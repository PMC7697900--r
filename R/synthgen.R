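#' Configuration of the synthetic accelerometer-signal generator
#'
#' Builds the parameter set for simulating 100 Hz lower-back accelerometer
#' streams: ADL recordings containing quiet standing with slow postural
#' drift, walking bouts and brief supra-threshold spike artifacts (the
#' false-alarm fodder), and fall recordings containing one multiphase fall
#' (free-fall dip, damped-oscillation impact loading at least two axes,
#' orientation flip of the gravity axis, then lying still or recovery).
#' Per-axis output is clipped at the sensor range and every fall carries its
#' annotated impact sample.
#'
#' @param nSubjects number of subjects (all of them fallers).
#' @param nAdlSubjects how many subjects also have one ADL recording.
#' @param adlHoursPerSubject ADL recording length, hours.
#' @param nFallsTotal total fall recordings, spread heterogeneously over the
#'   subjects (each subject gets at least one).
#' @param fallRecordingS fall recording length, seconds.
#' @param walkingBoutRate walking bouts per hour in ADL recordings.
#' @param walkingBoutS walking bout duration range, seconds.
#' @param cadenceHz walking step-frequency range, Hz.
#' @param walkingAmpG walking vertical-acceleration amplitude range, g (kept
#'   low enough that walking alone stays below the 1.4 g peak threshold).
#' @param spikeRate supra-threshold non-fall spike events per hour.
#' @param spikePeakG spike norm-peak range, g.
#' @param freefallFloorG free-fall dip floor range, g.
#' @param impactPeakG fall impact norm-peak range, g, drawn before clipping.
#' @param lyingProb probability a fall ends in a long lie (no recovery).
#' @param recoveryDelayS delay before recovery movements, seconds.
#' @param noiseSdG per-axis Gaussian sensor noise SD, g.
#' @param fs sampling frequency, Hz.
#' @param rangeG per-axis clipping range, g.
#' @param seed root seed; every recording derives its own sub-seed from it.
#' @return a validated list of class `synthConfig`.
#' @export
synthConfig <- function(nSubjects = 10, nAdlSubjects = nSubjects,
                        adlHoursPerSubject = 0.2, nFallsTotal = 30,
                        fallRecordingS = 60,
                        walkingBoutRate = 6, walkingBoutS = c(10, 30),
                        cadenceHz = c(1.5, 2.5), walkingAmpG = c(0.1, 0.25),
                        spikeRate = 45, spikePeakG = c(1.6, 2.6),
                        freefallFloorG = c(0.3, 0.8),
                        impactPeakG = c(2.0, 3.5),
                        lyingProb = 0.6, recoveryDelayS = c(3, 8),
                        noiseSdG = 0.02, fs = 100, rangeG = 2, seed = 1) {
  cfg <- list(nSubjects = nSubjects, nAdlSubjects = nAdlSubjects,
              adlHoursPerSubject = adlHoursPerSubject,
              nFallsTotal = nFallsTotal, fallRecordingS = fallRecordingS,
              walkingBoutRate = walkingBoutRate,
              walkingBoutS = walkingBoutS, cadenceHz = cadenceHz,
              walkingAmpG = walkingAmpG, spikeRate = spikeRate,
              spikePeakG = spikePeakG, freefallFloorG = freefallFloorG,
              impactPeakG = impactPeakG, lyingProb = lyingProb,
              recoveryDelayS = recoveryDelayS, noiseSdG = noiseSdG,
              fs = fs, rangeG = rangeG, seed = seed)
  for (f in c("walkingBoutS", "cadenceHz", "walkingAmpG", "spikePeakG",
              "freefallFloorG", "impactPeakG", "recoveryDelayS"))
    if (length(cfg[[f]]) != 2L || diff(cfg[[f]]) < 0)
      stop("'", f, "' must be an ordered range of two values")
  if (min(cfg$impactPeakG) < 1.4)
    stop("impact peaks below 1.4 g would be undetectable by the windowing")
  if (cfg$nAdlSubjects > cfg$nSubjects)
    stop("nAdlSubjects cannot exceed nSubjects")
  if (cfg$nFallsTotal < cfg$nSubjects)
    stop("need at least one fall per subject")
  stopifnot(cfg$walkingBoutRate >= 0, cfg$spikeRate >= 0,
            cfg$lyingProb >= 0, cfg$lyingProb <= 1, cfg$noiseSdG >= 0)
  structure(cfg, class = "synthConfig")
}

.unit <- function(v) v / sqrt(sum(v^2))

# random unit vector roughly aligned with a random sensor axis
.randomUprightAxis <- function() {
  e <- numeric(3)
  e[sample.int(3, 1)] <- sample(c(-1, 1), 1)
  .unit(e + 0.15 * stats::rnorm(3))
}

# random unit vector with at least two substantial components
.impactDirection <- function(reference) {
  repeat {
    u <- .unit(stats::rnorm(3))
    if (sort(abs(u), decreasing = TRUE)[2] >= 0.3) break
  }
  if (sum(u * reference) < 0) u <- -u  # impact adds to, not cancels, gravity
  u
}

# geodesic interpolation between two unit vectors; w in [0, 1]
.slerp <- function(a, b, w) {
  dotp <- max(min(sum(a * b), 1), -1)
  th <- acos(dotp)
  if (th < 1e-8) return(matrix(rep(a, each = length(w)), ncol = 3))
  (sin((1 - w) * th) / sin(th)) %o% a + (sin(w * th) / sin(th)) %o% b
}

.runif1 <- function(range) stats::runif(1, range[1], range[2])

# add a tapered walking oscillation to acc[idx, ] along vertical/lateral dirs
.addWalking <- function(acc, idx, t, cadence, amp, vert, fs) {
  lat <- .unit(pracmaFreeOrtho(vert))
  tt <- t[idx] - t[idx[1]]
  taper <- pmin(1, tt / 1, (tt[length(tt)] - tt) / 1)^2
  phase <- 2 * pi * cadence * tt
  v <- amp * (sin(phase) + 0.3 * sin(2 * phase)) * taper
  l <- 0.3 * amp * sin(0.5 * phase) * taper
  acc[idx, ] <- acc[idx, ] + v %o% vert + l %o% lat
  acc
}

# any unit vector orthogonal to v
pracmaFreeOrtho <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(a - sum(a * v) * v)
}

.finishRecording <- function(acc, cfg, subjectId, recordingId, kind,
                             impactSample = NA) {
  n <- nrow(acc)
  acc <- acc + matrix(stats::rnorm(3L * n, 0, cfg$noiseSdG), n, 3)
  acc <- pmin(pmax(acc, -cfg$rangeG), cfg$rangeG)
  triaxialRecording(subjectId, recordingId, kind,
                    ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                    fs = cfg$fs, rangeG = cfg$rangeG,
                    impactSample = impactSample)
}

#' Simulate an ADL recording
#'
#' Gravity rides on a randomly oriented, slowly drifting vertical axis;
#' walking bouts add harmonic cadence components (too weak to cross the peak
#' threshold on their own); Poisson-placed spike artifacts exceed 1.4 g in
#' norm and are the source of candidate windows in ADL data; Gaussian sensor
#' noise and per-axis clipping complete the model.
#'
#' @param cfg a [synthConfig()].
#' @param subjectId subject identifier.
#' @param seed integer seed; fixed seed gives a bit-identical recording.
#' @param recordingId recording identifier.
#' @return a [TriaxialRecording-class] with `kind = "adl"`.
#' @export
simulateADLRecording <- function(cfg, subjectId, seed,
                                 recordingId = paste0(subjectId, "_adl")) {
  stopifnot(inherits(cfg, "synthConfig"))
  withr::with_seed(as.integer(seed), {
    dur <- cfg$adlHoursPerSubject * 3600
    n <- as.integer(round(dur * cfg$fs))
    t <- (0:(n - 1)) / cfg$fs
    g0 <- .randomUprightAxis()
    g1 <- .unit(g0 + 0.1 * stats::rnorm(3))
    w <- (1 - cos(2 * pi * t / dur)) / 2  # drift out and back, period = dur
    acc <- .slerp(g0, g1, w)
    hours <- dur / 3600
    nBouts <- stats::rpois(1, cfg$walkingBoutRate * hours)
    for (b in seq_len(nBouts)) {
      d <- .runif1(cfg$walkingBoutS)
      if (d >= dur) d <- dur / 2
      start <- stats::runif(1, 0, dur - d)
      idx <- which(t >= start & t < start + d)
      if (length(idx) < 2L) next
      acc <- .addWalking(acc, idx, t, .runif1(cfg$cadenceHz),
                         .runif1(cfg$walkingAmpG), g0, cfg$fs)
    }
    nSpikes <- stats::rpois(1, cfg$spikeRate * hours)
    for (s in seq_len(nSpikes)) {
      tc <- stats::runif(1, 1, max(dur - 1, 1))
      peak <- .runif1(cfg$spikePeakG)
      i0 <- as.integer(round(tc * cfg$fs))
      u <- .impactDirection(acc[min(i0 + 1L, n), ])
      amp <- sqrt(peak^2 - 1)  # norm(g + amp*u) >= peak when u . g >= 0
      idx <- which(abs(t - tc) <= 0.15)
      shape <- exp(-((t[idx] - tc)^2) / (2 * 0.04^2))
      ring <- 0.25 * sin(2 * pi * 15 * (t[idx] - tc)) * shape
      acc[idx, ] <- acc[idx, ] + (amp * (shape + ring)) %o% u
    }
    .finishRecording(acc, cfg, subjectId, recordingId, "adl")
  })
}

#' Simulate a fall recording
#'
#' A background stream (quiet standing, possibly a walking bout) with one
#' embedded multiphase fall: the norm dips to the free-fall floor for
#' 0.2-0.5 s, a damped oscillation loads at least two axes so the clipped norm
#' can exceed 2 g, the gravity axis flips to a lying orientation, and the
#' subject then lies still (probability `lyingProb`) or recovers and resumes
#' walking after `recoveryDelayS`. The annotated impact sample is the norm
#' argmax of the generated impact.
#'
#' @inheritParams simulateADLRecording
#' @return a [TriaxialRecording-class] with `kind = "fall"` and its
#'   `impactSample` set.
#' @export
simulateFallRecording <- function(cfg, subjectId, seed,
                                  recordingId = paste0(subjectId, "_fall")) {
  stopifnot(inherits(cfg, "synthConfig"))
  withr::with_seed(as.integer(seed), {
    dur <- cfg$fallRecordingS
    stopifnot(dur >= 40)
    n <- as.integer(round(dur * cfg$fs))
    t <- (0:(n - 1)) / cfg$fs
    gUp <- .randomUprightAxis()
    gLie <- .unit(pracmaFreeOrtho(gUp) + 0.2 * stats::rnorm(3))

    tFall <- stats::runif(1, 5, dur - 30)
    d1 <- .runif1(c(0.2, 0.5))
    floorG <- .runif1(cfg$freefallFloorG)
    tImpact <- tFall + d1
    lying <- stats::runif(1) < cfg$lyingProb
    tRecover <- tImpact + .runif1(cfg$recoveryDelayS)

    # gravity direction: upright until impact, flip to lying over 1 s
    w <- pmin(pmax((t - tImpact) / 1, 0), 1)
    w <- w^2 * (3 - 2 * w)  # smoothstep
    acc <- .slerp(gUp, gLie, w)
    if (!lying) {
      wb <- pmin(pmax((t - tRecover) / 1, 0), 1)
      wb <- wb^2 * (3 - 2 * wb)
      accBack <- .slerp(gLie, gUp, wb)
      after <- t >= tRecover
      acc[after, ] <- accBack[after, ]
    }

    # free-fall dip: gravity magnitude ramps 1 -> floor, held until impact
    dip <- t >= tFall & t < tImpact
    ramp <- pmin((t[dip] - tFall) / (0.4 * d1), 1)
    acc[dip, ] <- acc[dip, ] * (1 - (1 - floorG) * ramp)

    # impact: damped oscillation on a direction loading >= 2 axes
    peak <- .runif1(cfg$impactPeakG)
    u <- .impactDirection(gUp * floorG)
    amp <- sqrt(max(peak^2 - floorG^2, 0.5))
    imp <- t >= tImpact & t < tImpact + 0.4
    tau <- t[imp] - tImpact
    acc[imp, ] <- acc[imp, ] +
      (amp * cos(2 * pi * 12 * tau) * exp(-tau / 0.08)) %o% u

    # optional pre-fall walking bout ending at the fall onset
    if (stats::runif(1) < 0.5) {
      start <- max(0, tFall - .runif1(cfg$walkingBoutS))
      idx <- which(t >= start & t < tFall)
      if (length(idx) > 2L)
        acc <- .addWalking(acc, idx, t, .runif1(cfg$cadenceHz),
                           .runif1(cfg$walkingAmpG), gUp, cfg$fs)
    }
    # post-recovery walking
    if (!lying) {
      idx <- which(t >= tRecover + 1)
      if (length(idx) > 2L)
        acc <- .addWalking(acc, idx, t, .runif1(cfg$cadenceHz),
                           .runif1(cfg$walkingAmpG), gUp, cfg$fs)
    }

    rec <- .finishRecording(acc, cfg, subjectId, recordingId, "fall",
                            impactSample = 0L)
    nrm <- sqrt(rec@ax^2 + rec@ay^2 + rec@az^2)
    search <- which(t >= tFall & t <= tImpact + 0.5)
    rec@impactSample <- as.integer(search[which.max(nrm[search])] - 1L)
    validObject(rec)
    rec
  })
}

#' Simulate a full dataset of fall and ADL recordings
#'
#' Every subject receives at least one fall recording; the remaining falls are
#' spread with random (seeded) weights so per-subject fall counts are
#' heterogeneous, and the first `nAdlSubjects` subjects also receive one ADL
#' recording each — together this exercises the stratified fold assignment.
#' Each recording derives its own sub-seed from the root seed, so any single
#' recording can be regenerated in isolation.
#'
#' @param cfg a [synthConfig()].
#' @param dir optional directory; when given, recordings and a
#'   `manifest.json` are written there via [writeDataset()].
#' @return list with `recordings` (list of [TriaxialRecording-class]),
#'   `fallsPerSubject` (named integer) and `config`.
#' @export
simulateDataset <- function(cfg = synthConfig(), dir = NULL) {
  stopifnot(inherits(cfg, "synthConfig"))
  subjects <- sprintf("S%02d", seq_len(cfg$nSubjects))
  extra <- cfg$nFallsTotal - cfg$nSubjects
  wts <- withr::with_seed(as.integer(cfg$seed),
                          stats::rexp(cfg$nSubjects)^2)
  fallCounts <- 1L + withr::with_seed(
    as.integer(cfg$seed) + 1L,
    as.integer(stats::rmultinom(1, extra, wts / sum(wts))))
  names(fallCounts) <- subjects

  recordings <- list()
  salt <- 0L
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    if (i <= cfg$nAdlSubjects) {
      salt <- salt + 1L
      recordings <- c(recordings, list(simulateADLRecording(
        cfg, s, seed = .deriveSeed(cfg$seed, salt))))
    }
    for (j in seq_len(fallCounts[[s]])) {
      salt <- salt + 1L
      recordings <- c(recordings, list(simulateFallRecording(
        cfg, s, seed = .deriveSeed(cfg$seed, salt),
        recordingId = sprintf("%s_fall%02d", s, j))))
    }
  }
  if (!is.null(dir)) writeDataset(recordings, dir)
  list(recordings = recordings, fallsPerSubject = fallCounts, config = cfg)
}

#' Load a generator preset
#'
#' Reads a YAML file of [synthConfig()] arguments. The bundled preset
#' `"farseeing_like"` mirrors the scale of the FARSEEING real-world study
#' data: 15 subjects with 12-h ADL recordings (180 monitored hours) and 143
#' falls over 46 subjects. Simulating it in full is expensive; it exists to
#' document the reference scale, while the defaults keep desk-scale runs
#' fast.
#'
#' @param name preset name (bundled) or a path to a YAML file.
#' @return a [synthConfig()].
#' @export
loadPreset <- function(name = "farseeing_like") {
  path <- if (file.exists(name)) name
          else system.file("extdata", paste0(name, ".yaml"),
                           package = "multifall", mustWork = TRUE)
  args <- yaml::read_yaml(path)
  do.call(synthConfig, args)
}
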