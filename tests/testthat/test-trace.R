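test_that("Savitzky-Golay smoothing reproduces polynomials and cuts noise", {
  t <- seq_len(200)
  poly3 <- 2 + 0.5 * t - 0.01 * t^2 + 1e-4 * t^3
  expect_equal(smoothTrace(poly3, 11, 4), poly3, tolerance = 1e-8)
  ## noisy AP train: residual sd strictly reduced at window 11, order 4
  fx <- gapFreeTrain(100, 10, noiseSd = 0.2, seed = 1)
  clean <- gapFreeTrain(100, 10)$trace
  sm <- smoothTrace(fx$trace, 11, 4)
  expect_lt(sd(sm - clean), sd(fx$trace - clean))
  ## window 0/1 are identity; invalid parameters error
  expect_identical(smoothTrace(poly3, 0), poly3)
  expect_identical(smoothTrace(poly3, 1), poly3)
  expect_error(smoothTrace(poly3, 10, 4), "odd")
  expect_error(smoothTrace(poly3, 11, 11), "smaller")
})

test_that("drift removal subtracts the fitted polynomial, keeps the mean", {
  fx <- gapFreeTrain(80, 8)
  n <- length(fx$trace)
  ramp <- seq(0, 3, length.out = n)
  out <- subtractBaselineDrift(fx$trace + ramp, 1)
  expect_equal(mean(out), mean(fx$trace + ramp), tolerance = 1e-12)
  ## the fitted polynomial absorbs the ramp exactly: adding a linear drift
  ## changes the corrected trace only by the drift's mean
  ref <- subtractBaselineDrift(fx$trace, 1)
  expect_lt(sd(out - ref), 1e-9)
  expect_equal(mean(out - ref), mean(ramp), tolerance = 1e-9)
  ## quartic drift, degree 4
  u <- seq(-1, 1, length.out = n)
  quartic <- 2 * u^4 - u^2 + 0.3 * u
  out4 <- subtractBaselineDrift(fx$trace + quartic, 4)
  ref4 <- subtractBaselineDrift(fx$trace, 4)
  expect_lt(sd(out4 - ref4), 1e-9)
  ## constant trace is a fixed point
  expect_equal(subtractBaselineDrift(rep(2, 50), 3), rep(2, 50))
  expect_error(subtractBaselineDrift(rnorm(4), 4), "too short")
})

test_that("mean conservation holds across many random traces", {
  set.seed(33)
  for (i in 1:200) {
    tr <- rnorm(sample(50:300, 1), mean = runif(1, -5, 5))
    deg <- sample(0:5, 1)
    out <- subtractBaselineDrift(tr, deg)
    expect_lt(abs(mean(out) - mean(tr)) / max(abs(mean(tr)), 1), 1e-9)
  }
})

test_that("segmentation splits at diastoles inclusively", {
  tr <- rnorm(201)
  segs <- segmentActivations(tr, c(1, 101, 201))
  expect_length(segs, 2)
  expect_equal(lengths(lapply(segs, `[[`, "values")), c(101L, 101L))
  expect_equal(segs[[2]]$startFrame, 101)
  expect_equal(segs[[1]]$values[101], segs[[2]]$values[1])  # shared endpoint
  ## degenerate 2-sample segment is legal
  expect_length(segmentActivations(tr, c(5, 6)), 1)
  expect_error(segmentActivations(tr, 5), "at least 2")
  expect_error(segmentActivations(tr, c(10, 10)), "increasing")
})

test_that("thresholding interpolates crossings exactly on a tent", {
  tent <- makeTransientTemplate("apTent", 10, 10)  # 0..1..0 over 21 samples
  obj <- thresholdObjects(tent, 0.5)
  expect_equal(nrow(obj), 1)
  expect_equal(obj$start, 5)
  expect_equal(obj$end, 15)
  expect_equal(obj$duration, 10)
  ## nothing above threshold -> empty result
  expect_equal(nrow(thresholdObjects(tent, 2)), 0)
  ## run touching the boundary uses the boundary sample time
  expect_equal(thresholdObjects(c(1, 0.4, 0.2), 0.3)$start, 0)
})

test_that("split transients yield ordered objects; oversampling agrees", {
  two <- c(0, 1, 0.1, 0, 0.8, 0)
  obj <- thresholdObjects(two, 0.5)
  expect_equal(nrow(obj), 2)
  expect_true(all(diff(obj$start) > 0))
  ## dense-grid oracle: crossings of a random smooth segment
  set.seed(2)
  x <- cumsum(rnorm(30)); x <- x - min(x)
  thr <- stats::quantile(x, 0.5)
  obj <- thresholdObjects(x, thr)
  fine <- seq(0, 29, by = 0.001)
  xf <- approx(0:29, x, fine)$y
  runs <- rle(xf > thr)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  fs <- fine[starts[runs$values]]; fe <- fine[ends[runs$values]]
  expect_length(obj$start, length(fs))
  expect_true(all(abs(obj$start - fs) < 2e-3))
  expect_true(all(abs(obj$end - fe) < 2e-3))
})

test_that("object selection honours first/largest/augmented rules", {
  objs <- data.frame(start = c(5, 30), end = c(15, 32),
                     duration = c(10, 2))
  expect_equal(selectObject(objs, "largest")$start, 5)
  expect_equal(selectObject(objs, "first")$start, 5)
  expect_equal(selectObject(objs, "augmented", upstrokeTime = 29)$start, 30)
  expect_equal(selectObject(objs, "augmented", upstrokeTime = 10)$start, 5)
  expect_null(selectObject(objs[0, ], "first"))
  expect_error(selectObject(objs, "augmented"), "upstrokeTime")
})

test_that("tent features match closed forms at several recovery levels", {
  tent <- makeTransientTemplate("apTent", 10, 10)
  for (lvl in c(0.5, 0.8, 0.9)) {
    p <- rawParams(recoveryLevel = lvl)
    f <- extractFeatures(tent, p)
    truth <- analyticTransientFeatures("apTent", 10, 10, level = lvl)
    expect_equal(f$durationMs, truth$durationFrames, tolerance = 1e-12)
    expect_equal(f$activationTimeMs, truth$activationFrames,
                 tolerance = 1e-12)
    expect_equal(f$recoveryTimeMs, truth$recoveryFrames, tolerance = 1e-12)
    expect_equal(f$amplitude, 1)
    expect_equal(f$baseline, 0)
  }
})

test_that("firstlast baseline shifts every crossing consistently", {
  ## tent that ends above baseline: last sample 0.2
  seg <- c(makeTransientTemplate("apTent", 10, 10)[1:19], 0.2, 0.2)
  p <- rawParams(recoveryLevel = 0.8, baselineMode = "firstlast")
  f <- extractFeatures(seg, p)
  base <- (0 + 0.2) / 2
  amp <- 1 - base
  expect_equal(f$baseline, base)
  expect_equal(f$amplitude, amp)
  thr <- base + 0.2 * amp                 # = 0.28
  ## closed-form crossings on the tent (rise t/10, fall 2 - t/10)
  expect_equal(f$durationMs, (20 - 10 * thr) - 10 * thr, tolerance = 1e-12)
  half <- base + 0.5 * amp
  expect_equal(f$activationTimeMs, 10 * half, tolerance = 1e-12)
})

test_that("downward voltage-style tents give identical features", {
  tentUp <- c(rep(0, 20), makeTransientTemplate("apTent", 10, 10),
              rep(0, 20))
  tentDown <- -tentUp
  fU <- extractFeatures(tentUp, rawParams())
  fD <- extractFeatures(tentDown, rawParams(polarity = "troughs"))
  expect_equal(fD$durationMs, fU$durationMs, tolerance = 1e-12)
  expect_equal(fD$amplitude, fU$amplitude, tolerance = 1e-12)
  expect_equal(fD$activationTimeMs, fU$activationTimeMs, tolerance = 1e-12)
  expect_equal(fD$recoveryTimeMs, fU$recoveryTimeMs, tolerance = 1e-12)
})

test_that("duration decreases as the recovery level decreases", {
  tpl <- makeTransientTemplate("catSkewed", 5, 60)
  levels <- seq(0.1, 0.9, by = 0.1)
  durs <- vapply(levels, function(l)
    extractFeatures(tpl, rawParams(recoveryLevel = l))$durationMs,
    numeric(1))
  expect_true(all(diff(durs) >= 0))  # higher level -> longer duration
})

test_that("augmented selection rejects a spurious early noise object", {
  tent <- makeTransientTemplate("apTent", 10, 10)
  seg <- c(rep(0, 5), 0.9, rep(0, 14), tent, rep(0, 10))  # noise spike first
  upstroke <- 5 + 14 + 1 + 5  # on the true transient's rise
  fFirst <- extractFeatures(seg, rawParams(objectSelection = "first"))
  fAug <- extractFeatures(seg, rawParams(objectSelection = "augmented"),
                          upstrokeTime = upstroke,
                          segmentStartGlobal = 1)
  expect_lt(fFirst$durationMs, 2)          # grabbed the spike
  expect_equal(fAug$durationMs, 16, tolerance = 1e-9)  # the real APD80
  expect_false(fFirst$durationMs == fAug$durationMs)
})

test_that("pathological segments yield missing records, not errors", {
  expect_false(extractFeatures(rep(1, 20), rawParams())$ok)   # flat
  expect_false(extractFeatures(c(1, 0.5), rawParams())$ok)    # no up-cross
})

test_that("clock normalization subtracts the preceding boundary", {
  clk <- recordingClock(c(426, 568, 710))  # boundaries 497, 639
  nb <- normalizeToClock(568.79, clk)
  expect_equal(nb$relativeTimeMs, 71.79)
  expect_equal(nb$binIndex, 1L)
  ## exactly on a boundary
  on <- normalizeToClock(497, clk)
  expect_equal(on$relativeTimeMs, 0)
  expect_equal(on$binIndex, 1L)
  ## outside the clock range -> unassigned
  expect_true(is.na(normalizeToClock(400, clk)$binIndex))
  expect_true(is.na(normalizeToClock(639, clk)$binIndex))
  expect_true(is.na(normalizeToClock(700, clk)$binIndex))
})

test_that("trace parameter validation rejects bad settings", {
  expect_error(traceParams(smoothingWindow = 10), "odd")
  expect_error(traceParams(recoveryLevel = 1), "strictly between")
  expect_error(traceParams(refinementWidthMs = -1), "non-negative")
  expect_error(recordingClock(c(1, 2)), "at least 3")
})
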