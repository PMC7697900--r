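test_that("lower and upper peak values read the intended phases", {
  w <- makeCFW(prePeak = rep(1, 100), peak = 2.5)
  expect_equal(lowerPeakValue(w), 1)
  expect_equal(upperPeakValue(w), 2.5)
  w2 <- makeCFW(prePeak = seq(1, 0.4, length.out = 100), peak = 2.0)
  expect_equal(lowerPeakValue(w2), 0.4)
})

test_that("LPV never exceeds UPV and UPV respects the emission threshold", {
  ds <- sharedDataset()
  col <- collectCFWs(ds$recordings)
  for (w in col$cfws) {
    expect_lte(lowerPeakValue(w), upperPeakValue(w))
    expect_gte(upperPeakValue(w), 1.4)
  }
})

test_that("the mother wavelet is the normalized mean impact segment", {
  shape <- 1 + 0.5 * sin(2 * pi * 3 * (0:200) / 201)
  w <- makeCFW(prePeak = shape[1:100], peak = max(shape) + 1.4,
               postPeak = shape[102:201])
  # rebuild the CFW so the impact segment is exactly `shape`
  w@norm[1:201] <- shape
  tmpl <- buildMotherWavelet(list(w))
  expected <- shape - mean(shape)
  expected <- expected / sqrt(sum(expected^2))
  expect_equal(tmpl@values, expected, tolerance = 1e-12)
  expect_identical(tmpl@nTrainingFalls, 1L)
  # averaging two identical falls changes nothing
  tmpl2 <- buildMotherWavelet(list(w, w))
  expect_equal(tmpl2@values, tmpl@values, tolerance = 1e-12)
  expect_error(buildMotherWavelet(list()), "zero training falls")
})

test_that("wavelet similarity is a normalized correlation", {
  i <- 0:200
  sinSeg <- 1.5 + 0.2 * sin(2 * pi * 5 * i / 201)
  cosSeg <- 1.5 + 0.2 * cos(2 * pi * 5 * i / 201)  # orthogonal to sinSeg
  wA <- makeCFW(); wA@norm[1:201] <- sinSeg
  tmpl <- buildMotherWavelet(list(wA, wA))
  expect_equal(waveletSimilarity(wA, tmpl), 1, tolerance = 1e-9)
  wB <- makeCFW(); wB@norm[1:201] <- cosSeg
  expect_equal(waveletSimilarity(wB, tmpl), 0, tolerance = 1e-9)
  wC <- makeCFW(); wC@norm[1:201] <- 3 - sinSeg  # inverted shape
  expect_equal(waveletSimilarity(wC, tmpl), -1, tolerance = 1e-9)
  # zero-variance segment scores 0 by definition
  wD <- makeCFW(); wD@norm[1:201] <- 1.7
  expect_equal(waveletSimilarity(wD, tmpl), 0)
})

test_that("periodicity is high for cadenced motion, near zero otherwise", {
  t <- (0:2650) / 100
  w <- makeCFW()
  w@norm <- 1 + 0.3 * sin(2 * pi * 2 * t)  # 2 Hz, walking-like
  w@norm[101] <- 2.5
  expect_gte(periodicityAfterImpact(w), 0.9)
  wConst <- makeCFW()
  expect_equal(periodicityAfterImpact(wConst), 0)
  # white-noise segments: frozen Monte-Carlo bounds from the pairwise
  # correlation oracle (200 draws)
  scores <- withr::with_seed(31, replicate(200, {
    wn <- makeCFW()
    wn@norm <- abs(1 + rnorm(2651, sd = 0.1))
    periodicityAfterImpact(wn)
  }))
  expect_lte(mean(scores), 0.25)
  expect_lte(unname(quantile(scores, 0.95)), 0.35)
  expect_true(all(scores >= 0 & scores <= 1))
})

test_that("post-impact SD uses the sample convention on the right segment", {
  w <- makeCFW(postImpact = rep(1, 2450))
  expect_equal(postImpactSD(w), 0)
  w2 <- makeCFW(postImpact = rep(c(0.9, 1.1), 1225))
  expect_equal(postImpactSD(w2), sqrt(2450 * 0.01 / 2449))  # ~0.1000
  expect_equal(round(postImpactSD(w2), 4), 0.1)
  # direct-formula check on an arbitrary segment
  seg <- withr::with_seed(32, abs(rnorm(2450, 1, 0.2)))
  w3 <- makeCFW(postImpact = seg)
  expect_equal(postImpactSD(w3), sd(seg))
})

test_that("conventional features are the 16 per-channel statistics", {
  w <- makeCFWFromAxes(ax = rep(0, 2651), ay = rep(0, 2651),
                       az = rep(1, 2651))
  f <- conventionalFeatures(w)
  expect_length(f, 16)
  expect_equal(unname(f["az_max"]), 1)
  expect_equal(unname(f["az_min"]), 1)
  expect_equal(unname(f["az_sd"]), 0)
  # brute-force recomputation on a random CFW
  ds <- sharedDataset()
  w2 <- collectCFWs(ds$recordings)$cfws[[1]]
  f2 <- conventionalFeatures(w2)
  m <- axisMatrix(w2)
  expect_equal(unname(f2["ax_mean"]), mean(m[, "ax"]))
  expect_equal(unname(f2["ay_min"]), min(m[, "ay"]))
  expect_equal(unname(f2["norm_max"]), max(normValues(w2)))
  expect_equal(unname(f2["norm_sd"]), sd(normValues(w2)))
})

test_that("feature tables have the documented shape and are pure", {
  ds <- sharedDataset()
  cfws <- collectCFWs(ds$recordings)$cfws[1:3]
  falls <- Filter(function(w) cfwLabel(w) == "fall",
                  collectCFWs(ds$recordings)$cfws)
  tmpl <- buildMotherWavelet(falls)
  tab <- extractFeatures(cfws, "multiphase", tmpl)
  expect_equal(nrow(tab), 3)
  expect_identical(featureColumns(tab), featureNames("multiphase"))
  expect_length(featureNames("multiphase"), 5)
  expect_length(featureNames("conventional"), 16)
  expect_false(anyNA(tab))
  expect_identical(tab, extractFeatures(cfws, "multiphase", tmpl))
  expect_equal(nrow(extractFeatures(list(), "conventional")), 0)
  expect_error(extractFeatures(cfws, "multiphase"), "template")
})

test_that("multiphase features are orientation-invariant, conventional not", {
  ds <- sharedDataset()
  fall <- Filter(function(r) recordingKind(r) == "fall", ds$recordings)[[1]]
  permute <- function(rec) {
    # swap x/z and flip y: a rigid re-mounting of the sensor
    triaxialRecording(subjectId(rec), recordingId(rec), recordingKind(rec),
                      ax = rec@az, ay = -rec@ay, az = rec@ax,
                      rangeG = rec@rangeG,
                      impactSample = impactSample(rec))
  }
  runPipe <- function(rec, featureSet, tmplCfws = NULL) {
    r2 <- clipToRange(rec, 2)
    cfws <- findCFWs(computeNorm(r2), r2)
    tmpl <- buildMotherWavelet(cfws[1])
    extractFeatures(cfws, featureSet, tmpl)
  }
  orig <- runPipe(fall, "multiphase")
  perm <- runPipe(permute(fall), "multiphase")
  expect_identical(orig[, featureNames("multiphase")],
                   perm[, featureNames("multiphase")])
  origC <- runPipe(fall, "conventional")
  permC <- runPipe(permute(fall), "conventional")
  expect_false(isTRUE(all.equal(origC[, featureNames("conventional")],
                                permC[, featureNames("conventional")])))
})

test_that("feature values respect their documented ranges", {
  ds <- sharedDataset()
  col <- collectCFWs(ds$recordings)
  falls <- Filter(function(w) cfwLabel(w) == "fall", col$cfws)
  tmpl <- buildMotherWavelet(falls)
  tab <- extractFeatures(col$cfws, "multiphase", tmpl)
  expect_true(all(tab$wavelet_similarity >= -1 & tab$wavelet_similarity <= 1))
  expect_true(all(tab$periodicity >= 0 & tab$periodicity <= 1))
  expect_true(all(tab$post_impact_sd >= 0))
})
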