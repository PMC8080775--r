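## Shared helpers: independent oracles and common fixture shortcuts.

## Brute-force comb positioning: plain loop over every placement, kept
## deliberately independent of combDetect's vectorised search.
bruteForceBestShift <- function(trace, offsets, polarity) {
  span <- offsets[length(offsets)]
  shifts <- 0:(length(trace) - span - 1L)
  objs <- vapply(shifts, function(o) {
    s <- 0
    for (k in offsets) s <- s + trace[o + k + 1L]
    s / length(offsets)
  }, numeric(1))
  best <- if (polarity == "troughs") which.min(objs) else which.max(objs)
  shifts[best]
}

## Analysis parameters with preprocessing disabled, for exactness tests.
rawParams <- function(...) {
  traceParams(smoothingWindow = 0L, driftPolyDegree = -1L, ...)
}

## Gap-free calcium-style train: template spans exactly one BCL so the
## unique per-beat minima sit at the stimulus frames.
gapFreeTrain <- function(bcl, nBeats, rise = max(2L, bcl %/% 10L),
                         noiseSd = 0, seed = NULL, alternansA = 0) {
  tpl <- makeTransientTemplate("catSkewed", rise, bcl - 1L - rise)
  makeTrace(tpl, rep(bcl, nBeats - 1L), nFrames = nBeats * bcl,
            noiseSd = noiseSd, seed = seed, alternansA = alternansA)
}

## Tent-transient flash stack: every pixel carries the same tent train.
tentFlashStack <- function(rows = 6, cols = 5, bcl = 60, nBeats = 4,
                           rise = 10, fall = 10, noiseSd = 0,
                           seed = NULL, alternansA = 0) {
  tpl <- makeTransientTemplate("apTent", rise, fall)
  makePlanarWaveStack(rows, cols, speedPxPerFrame = Inf, bclFrames = bcl,
                      nBeats = nBeats, template = tpl, noiseSd = noiseSd,
                      seed = seed, alternansA = alternansA)
}
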