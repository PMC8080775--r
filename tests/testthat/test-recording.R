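test_that("recording clock boundaries sit midway between peaks", {
  fx <- tentFlashStack(rows = 4, cols = 4, bcl = 80, nBeats = 6)
  clk <- computeRecordingClock(fx$recording, periodFrames = 80,
                               params = rawParams())
  expect_length(peakTimes(clk), 6)
  truthPeaksMs <- fx$truth$peakFramesRow1 - 1
  expect_equal(peakTimes(clk), truthPeaksMs)
  expect_equal(clockBoundaries(clk),
               (truthPeaksMs[-6] + truthPeaksMs[-1]) / 2)
})

test_that("planar-wave clock peaks land near the true midpoints", {
  fx <- makePlanarWaveStack(rows = 10, cols = 8, speedPxPerFrame = 1,
                            bclFrames = 150, nBeats = 6)
  clk <- computeRecordingClock(fx$recording, periodFrames = 150,
                               params = rawParams())
  ## spatial averaging blurs the peak by at most the traversal time
  truthPeaks <- fx$truth$peakFramesRow1 - 1
  expect_true(all(abs(diff(peakTimes(clk)) - 150) <= 2))
  expect_length(clockBoundaries(clk), 5)
})

test_that("a 2-beat recording cannot produce a clock", {
  fx <- tentFlashStack(rows = 3, cols = 3, bcl = 80, nBeats = 2)
  expect_error(computeRecordingClock(fx$recording, periodFrames = 80,
                                     params = rawParams()),
               "insufficient waves|at least 3")
})

test_that("multi-wave activation maps reproduce the planar wave", {
  speed <- 1  # px/frame
  fx <- makePlanarWaveStack(rows = 12, cols = 8, speedPxPerFrame = speed,
                            bclFrames = 100, nBeats = 5)
  maps <- analyzeMultiwave(fx$recording, periodFrames = 100,
                           params = rawParams())
  act <- perBeatMaps(maps, "activationTime")
  for (b in seq_len(dim(act)[3])) {
    ramp <- act[, 1, b]
    fit <- stats::lm(ramp ~ seq_along(ramp))
    expect_equal(unname(coef(fit)[2]), 1 / speed, tolerance = 0.02)
    expect_true(all(abs(act[, , b] - ramp) < 1e-9))  # constant along cols
  }
})

test_that("per-beat activation maps agree across beats (clock sync)", {
  fx <- makePlanarWaveStack(rows = 10, cols = 6, speedPxPerFrame = 0.5,
                            bclFrames = 120, nBeats = 5)
  maps <- analyzeMultiwave(fx$recording, periodFrames = 120,
                           params = rawParams())
  act <- perBeatMaps(maps, "activationTime")
  dt <- frameInterval(fx$recording)
  for (b in 2:dim(act)[3])
    expect_true(all(abs(act[, , b] - act[, , 1]) <= dt, na.rm = TRUE))
})

test_that("flash-train duration maps are constant at the tent closed form", {
  fx <- tentFlashStack(rows = 6, cols = 5, bcl = 60, nBeats = 4,
                       rise = 10, fall = 10)
  maps <- analyzeMultiwave(fx$recording, periodFrames = 60,
                           params = rawParams())
  dur <- beatMeanMap(maps, "duration")
  truth <- analyticTransientFeatures("apTent", 10, 10, level = 0.8)
  expect_true(all(abs(dur - truth$durationFrames) < 1e-9))
  amp <- beatMeanMap(maps, "amplitude")
  expect_true(all(abs(amp - 1) < 1e-9))
})

test_that("alternating amplitudes appear per beat exactly", {
  a <- 0.2
  fx <- tentFlashStack(rows = 4, cols = 4, bcl = 60, nBeats = 6,
                       alternansA = a)
  maps <- analyzeMultiwave(fx$recording, periodFrames = 60,
                           params = rawParams())
  amp <- perBeatMaps(maps, "amplitude")
  ## interior bins alternate between (1-a) and (1+a) patterns; which phase
  ## lands in bin 1 depends on which beats the clock brackets
  vals <- apply(amp, 3, function(m) m[1, 1])
  expect_equal(sort(unique(round(vals, 9))), c(1 - a, 1 + a))
  expect_true(all(abs(diff(vals)) > 0.3))  # strict alternation
})

test_that("no feature ever lands on a masked pixel", {
  mask <- matrix(TRUE, 6, 5); mask[2, ] <- FALSE; mask[, 3] <- FALSE
  fx <- tentFlashStack(rows = 6, cols = 5, bcl = 60, nBeats = 4)
  rec <- applyMask(fx$recording, mask)
  maps <- analyzeMultiwave(rec, periodFrames = 60, params = rawParams())
  for (f in featureNames(maps)) {
    a <- perBeatMaps(maps, f)
    for (b in seq_len(dim(a)[3]))
      expect_true(all(is.na(a[, , b][!mask])))
    expect_true(all(is.na(beatMeanMap(maps, f)[!mask])))
  }
  ## all-false mask: nothing to average for the clock
  expect_error(analyzeMultiwave(applyMask(fx$recording,
                                          matrix(FALSE, 6, 5)),
                                periodFrames = 60, params = rawParams()),
               "mask")
})

test_that("each pixel contributes at most one record per clock bin", {
  fx <- makePlanarWaveStack(rows = 8, cols = 6, speedPxPerFrame = 1,
                            bclFrames = 90, nBeats = 5)
  expect_silent({
    maps <- analyzeMultiwave(fx$recording, periodFrames = 90,
                             params = rawParams())
  })
  amp <- perBeatMaps(maps, "amplitude")
  expect_true(all(!is.na(amp)))  # regular pacing fills every bin once
})

test_that("single-wave analysis reports global times and staggered onsets", {
  tpl <- makeTransientTemplate("apTent", 10, 10)
  rows <- 6
  arr <- array(0, dim = c(rows, 4, 80))
  for (r in seq_len(rows)) {
    tr <- numeric(80)
    s <- 10 + (r - 1) * 3
    tr[s:(s + 20)] <- tpl
    arr[r, , ] <- matrix(tr, 4, 80, byrow = TRUE)
  }
  maps <- analyzeSinglewave(OMRecording(arr, 1), params = rawParams())
  act <- beatMeanMap(maps, "activationTime")
  ## activation at (s - 1) + 5 ms global (frame 1 = 0 ms, half-rise at 5)
  expect_equal(act[, 1], (10 + (seq_len(rows) - 1) * 3 - 1) + 5,
               tolerance = 1e-9)
  ## flat pixels yield missing records
  arrFlat <- arr; arrFlat[1, , ] <- 0.5
  mapsF <- analyzeSinglewave(OMRecording(arrFlat, 1), params = rawParams())
  expect_true(is.na(beatMeanMap(mapsF, "duration")[1, 1]))
})

test_that("hybrid equals single-wave on noise-free periodic input", {
  fx <- tentFlashStack(rows = 5, cols = 4, bcl = 60, nBeats = 6)
  hyb <- analyzeHybrid(fx$recording, 60, params = rawParams())
  sub <- averageSubstacks(fx$recording, 60, params = rawParams())
  sw <- analyzeSinglewave(sub$recording, params = rawParams())
  for (f in c("amplitude", "duration"))
    expect_equal(beatMeanMap(hyb, f), beatMeanMap(sw, f))
  ## averaging identical substacks is idempotent: closed-form tent APD80
  expect_true(all(abs(beatMeanMap(hyb, "duration") - 16) < 1e-9))
})

test_that("hybrid averaging reduces noise like the root of the beat count", {
  sigma <- 0.3; nBeats <- 16
  fx <- tentFlashStack(rows = 4, cols = 4, bcl = 50, nBeats = nBeats + 1,
                       noiseSd = sigma, seed = 77)
  clean <- tentFlashStack(rows = 4, cols = 4, bcl = 50, nBeats = nBeats + 1)
  sub <- averageSubstacks(fx$recording, 50, params = rawParams())
  subClean <- averageSubstacks(clean$recording, 50, params = rawParams())
  expect_equal(sub$nSubstacks, nBeats)
  resid <- intensityData(sub$recording) - intensityData(subClean$recording)
  expect_equal(sd(resid), sigma / sqrt(nBeats), tolerance = 0.2)
})

test_that("hybrid averages alternans away to the beat mean", {
  a <- 0.2
  fx <- tentFlashStack(rows = 4, cols = 4, bcl = 60, nBeats = 8,
                       alternansA = a)
  hyb <- analyzeHybrid(fx$recording, 60, params = rawParams())
  ## even/odd amplitudes 1+a and 1-a average to ~1
  expect_true(all(abs(beatMeanMap(hyb, "amplitude") - 1) < 0.05))
})

test_that("temporal SD maps flag jittered regions only", {
  fx <- tentFlashStack(rows = 6, cols = 4, bcl = 60, nBeats = 6)
  maps <- analyzeMultiwave(fx$recording, periodFrames = 60,
                           params = rawParams())
  sdMap <- temporalSdMap(maps, "duration")
  expect_true(all(sdMap < 1e-9, na.rm = TRUE))  # identical beats
  ## perturb the duration records of rows 1-2 and re-measure
  pb <- perBeatMaps(maps, "duration")
  set.seed(3)
  jitter <- 2
  pb[1:2, , ] <- pb[1:2, , ] + rnorm(length(pb[1:2, , ]), sd = jitter)
  maps2 <- maps
  maps2@perBeat$duration <- pb
  sd2 <- temporalSdMap(maps2, "duration")
  expect_gt(median(sd2[1:2, ]), jitter * 0.4)
  expect_true(all(sd2[3:6, ] < 1e-9))
  ## single-bin maps cannot have a temporal SD
  sw <- analyzeSinglewave(fx$recording, params = rawParams())
  expect_true(all(is.na(temporalSdMap(sw, "duration"))))
})

test_that("a custom comb recovers an S1-S2 activation pattern", {
  ## three S1 at 150 frames, one S2 coupled at 60 frames
  tpl <- makeTransientTemplate("catSkewed", 5, 40)
  fx <- makeTrace(tpl, c(150, 150, 60), nFrames = 600)
  cb <- customComb(c(150, 150, 60))
  ## the inter-beat gaps are flat zeros, so diastole ties are only broken
  ## deterministically with refinement off
  det <- combDetect(fx$trace, cb, "troughs", 0)
  expect_equal(toothPositions(det), fx$truth$stimulusFrames)
  peaks <- combDetect(fx$trace, cb, "peaks", 10)
  expect_equal(toothPositions(peaks), fx$truth$peakFrames)
})

test_that("the comb heuristic recovers intervals from the average trace", {
  fx <- tentFlashStack(rows = 4, cols = 4, bcl = 70, nBeats = 5)
  est <- estimateCustomComb(fx$recording, params = rawParams())
  expect_equal(diff(toothOffsets(est$comb)), rep(70L, 4))
  expect_equal(est$peakFrames, fx$truth$peakFramesRow1)
})
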