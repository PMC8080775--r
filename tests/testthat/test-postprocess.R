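test_that("activation-map plots are written for ramps and constants", {
  act <- outer(0:9, rep(1, 8)) * 3  # 0..27 ms down the rows
  f <- withr::local_tempfile(fileext = ".png")
  plotActivationMap(act, f, isochroneStepMs = 5)
  expect_true(file.exists(f) && file.size(f) > 0)
  ## constant map: single level, no crash
  g <- withr::local_tempfile(fileext = ".png")
  plotActivationMap(matrix(2, 5, 5), g)
  expect_true(file.exists(g) && file.size(g) > 0)
  expect_error(plotActivationMap(matrix(NA_real_, 5, 5), tempfile()),
               "missing")
  expect_error(plotActivationMap(matrix(0, 2, 2), tempfile()), "3x3")
})

test_that("point-to-point CV matches closed forms on a planar map", {
  act <- outer(0:15, rep(1, 8)) * 2  # T = r*2 ms down the rows
  pitch <- 0.1
  v <- cvBetweenPoints(act, cbind(1, 1, 11, 1), pitch)
  expect_equal(v, 0.05)
  ## diagonal pair: distance 5 px, dT 6 ms
  vd <- cvBetweenPoints(act, cbind(1, 1, 4, 5), pitch)
  expect_equal(vd, 0.5 / 6)
  ## pair independence along the propagation axis
  vAll <- cvBetweenPoints(act, cbind(c(1, 3, 5), 2, c(6, 8, 10), 2), pitch)
  expect_true(all(abs(vAll - 0.05) < 1e-12))
  ## degenerate and invalid pairs
  expect_warning(vEq <- cvBetweenPoints(act, cbind(3, 1, 3, 5), pitch),
                 "tolerance")
  expect_true(is.na(vEq))
  expect_error(cvBetweenPoints(act, cbind(0, 1, 3, 5), pitch), "outside")
})

test_that("local CV is exact on a linear activation surface", {
  v0 <- 0.5; pitch <- 0.1
  ## T = x / v0 with x along columns
  act <- outer(rep(1, 14), (0:13) * pitch) / v0
  vf <- baylyLocalCv(act, 3, pitch)
  expect_true(all(velocityValid(vf)))
  cmp <- velocityComponents(vf)
  expect_equal(max(abs(cmp$vx - v0)), 0, tolerance = 1e-9)
  expect_equal(max(abs(cmp$vy)), 0, tolerance = 1e-9)
  expect_equal(max(abs(velocitySpeed(vf) - v0)), 0, tolerance = 1e-9)
})

test_that("local CV recovers a circular target wave outside its core", {
  v0 <- 0.5; pitch <- 0.1
  n <- 21; ctr <- 11
  act <- outer(seq_len(n), seq_len(n), function(r, c)
    sqrt((r - ctr)^2 + (c - ctr)^2) * pitch / v0)
  ## curved fronts need a small window: the quadratic surface is only a
  ## local approximation of the cone
  vf <- baylyLocalCv(act, 1, pitch)
  sp <- velocitySpeed(vf)
  dist <- outer(seq_len(n), seq_len(n), function(r, c)
    sqrt((r - ctr)^2 + (c - ctr)^2))
  outside <- dist > 3 & velocityValid(vf)
  expect_true(all(abs(sp[outside] - v0) / v0 < 0.05))
  ## direction is radially outward
  cmp <- velocityComponents(vf)
  rr <- row(sp) - ctr; cc <- col(sp) - ctr
  dot <- (cmp$vx * cc + cmp$vy * rr) /
    (sqrt(cmp$vx^2 + cmp$vy^2) * pmax(dist, 1e-9))
  expect_true(all(dot[outside] > 0.99))
})

test_that("a constant activation surface yields no valid velocity", {
  vf <- baylyLocalCv(matrix(5, 10, 10), 3, 0.1)
  expect_false(any(velocityValid(vf)))
})

test_that("windows with too few valid pixels are invalid", {
  act <- outer(rep(1, 9), (0:8)) * 1.0
  act[, 4:9] <- NA  # leaves 3-wide strip: 3x(2w+1) windows still >= 6 at w=1
  vf <- baylyLocalCv(act, 1, 0.1)
  expect_false(any(velocityValid(vf)[, 4:9]))
})

test_that("alternans metrics follow their printed formulas exactly", {
  ## even/odd amplitudes A(1 +/- a)
  a <- 0.2
  pb <- array(NA_real_, dim = c(3, 3, 4))
  pb[, , c(1, 3)] <- 1 + a
  pb[, , c(2, 4)] <- 1 - a
  expect_equal(unique(as.vector(
    alternansValues(alternansMap(pb, "amplitude", "smape")))), a)
  expect_equal(unique(as.vector(
    alternansValues(alternansMap(pb, "amplitude", "largeToSmall")))), 1.5)
  expect_equal(unique(as.vector(
    alternansValues(alternansMap(pb, "amplitude", "oneMinusRatio")))),
    1 / 3, tolerance = 1e-12)
  ## no alternans: ratio 1, differences 0
  pbEq <- array(2, dim = c(3, 3, 4))
  expect_true(all(alternansValues(alternansMap(pbEq, "x",
                                               "largeToSmall")) == 1))
  expect_true(all(alternansValues(alternansMap(pbEq, "x", "smape")) == 0))
})

test_that("cross-metric identities hold on random positive maps", {
  set.seed(21)
  pb <- array(runif(5 * 5 * 6, 0.5, 3), dim = c(5, 5, 6))
  l2s <- alternansValues(alternansMap(pb, "x", "largeToSmall"))
  sm <- alternansValues(alternansMap(pb, "x", "smape"))
  omr <- alternansValues(alternansMap(pb, "x", "oneMinusRatio"))
  expect_equal(omr, 1 - 1 / l2s, tolerance = 1e-12)
  expect_equal(sm, (l2s - 1) / (l2s + 1), tolerance = 1e-12)
})

test_that("alternans is invariant to bin-parity shifts", {
  set.seed(8)
  pb <- array(rep(runif(5 * 5, 1, 2), 6) *
                rep(rep(c(1.3, 0.7), 3), each = 25),
              dim = c(5, 5, 6))
  shifted <- pb[, , 2:6, drop = FALSE]  # drop the first beat
  for (m in c("largeToSmall", "smape")) {
    v1 <- alternansValues(alternansMap(pb, "x", m))
    v2 <- alternansValues(alternansMap(shifted, "x", m))
    expect_equal(v1, v2, tolerance = 1e-12)
  }
})

test_that("non-positive even/odd means are flagged and dropped", {
  pb <- array(1, dim = c(2, 2, 2))
  pb[1, 1, 2] <- -1
  expect_warning(am <- alternansMap(pb, "x", "smape"), "non-positive")
  expect_true(is.na(alternansValues(am)[1, 1]))
  expect_false(anyNA(alternansValues(am)[2, ]))
  expect_error(alternansMap(array(1, c(2, 2, 1)), "x", "smape"),
               "at least 2 bins")
})

test_that("discordant fixtures show opposite phases split by a nodal line", {
  a <- 0.2
  fx <- makeDiscordantAlternansStack(rows = 11, cols = 6, a = a,
                                     nodalRow = 6, bclFrames = 80,
                                     nBeats = 6)
  maps <- analyzeMultiwave(fx$recording, periodFrames = 80,
                           params = rawParams())
  sm <- alternansMap(maps, "amplitude", "smape")
  v <- alternansValues(sm)
  expect_true(all(abs(v[c(1:5, 7:11), ] - a) < 1e-6))
  expect_true(all(v[6, ] < 1e-6))
  ## phases are opposite: even-mean map bright on one side, dim on the other
  eo <- alternansEvenOdd(sm)
  contrast <- eo$even - eo$odd
  expect_true(all(contrast[1:5, ] * contrast[7:11, ] < 0))
})
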