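featureSet <- c("baseline", "amplitude", "duration", "recoveryTime",
                "activationTime")

## Spatial average trace over unmasked pixels, preprocessed per params.
globalAverageTrace <- function(rec, params) {
    d <- intensityData(rec)
    m <- recordingMask(rec)
    dm <- dim(d)
    flat <- matrix(d, nrow = dm[1L] * dm[2L], ncol = dm[3L])
    if (!is.null(m)) {
        if (!any(m)) stop("mask excludes every pixel")
        flat <- flat[as.vector(m), , drop = FALSE]
    }
    tr <- colMeans(flat)
    tr <- smoothTrace(tr, params$smoothingWindow, params$smoothingOrder)
    if (params$driftPolyDegree >= 0L)
        tr <- subtractBaselineDrift(tr, params$driftPolyDegree)
    tr
}

## Resolve a uniform comb from periodFrames, or pass a custom Comb through.
resolveComb <- function(periodFrames = NULL, comb = NULL, nFrames) {
    if (is.null(comb)) {
        if (is.null(periodFrames))
            stop("supply either 'periodFrames' or a custom 'comb'")
        comb <- uniformComb(periodFrames, nFrames)
    }
    stopifnot(is(comb, "Comb"))
    comb
}

#' Compute the recording clock from the spatial average trace
#'
#' Peak activations of the whole-recording average trace are found with the
#' comb algorithm (maxima for upward/calcium-style signal, minima for
#' downward/voltage-style), and the clock boundaries are the midpoints
#' between consecutive peaks. At least three wave passes are required so
#' that at least two boundaries (one complete bin) exist.
#'
#' @param rec an [OMRecording-class].
#' @param periodFrames pacing period in frames (uniform comb), or NULL if a
#'   custom \code{comb} is given.
#' @param comb optional custom [Comb-class].
#' @param params a [traceParams()] object; its polarity, smoothing and
#'   drift settings are applied to the average trace.
#' @return A [RecordingClock-class].
#' @export
computeRecordingClock <- function(rec, periodFrames = NULL, comb = NULL,
                                  params = traceParams()) {
    stopifnot(is(rec, "OMRecording"))
    comb <- resolveComb(periodFrames, comb, nFrames(rec))
    if (nTeeth(comb) < 3L)
        stop("insufficient waves: the recording clock needs at least 3 ",
             "peak activations, comb has ", nTeeth(comb), " teeth")
    tr <- globalAverageTrace(rec, params)
    pol <- if (params$polarity == "peaks") "peaks" else "troughs"
    det <- combDetect(tr, comb, polarity = pol,
                      refinementWidthMs = params$refinementWidthMs,
                      frameIntervalMs = frameInterval(rec))
    peaksMs <- (toothPositions(det) - 1) * frameInterval(rec)
    recordingClock(peaksMs)
}

## Shared per-pixel feature extraction machinery. binOf(featList, pixelCtx)
## decides the bin; returns NA to drop the record.
emptyMaps <- function(nr, nc, nBins) {
    out <- lapply(featureSet, function(f)
        array(NA_real_, dim = c(nr, nc, nBins)))
    names(out) <- featureSet
    out
}

finishFeatureMaps <- function(perBeat, frameIntervalMs, mode, clock) {
    beatMean <- lapply(perBeat, function(a)
        apply(a, c(1L, 2L), function(v)
            if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)))
    spatialMeanPerBeat <- lapply(perBeat, function(a)
        apply(a, 3L, function(v)
            if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)))
    grandMean <- vapply(perBeat, function(a)
        if (all(is.na(a))) NA_real_ else mean(a, na.rm = TRUE), numeric(1))
    new("FeatureMaps", perBeat = perBeat, beatMean = beatMean,
        spatialMeanPerBeat = spatialMeanPerBeat, grandMean = grandMean,
        frameIntervalMs = frameIntervalMs, mode = mode, clock = clock)
}

#' Multi-wave analysis of a paced recording
#'
#' The full per-beat pipeline: a recording clock is computed on the spatial
#' average trace; then for every analysed pixel its trace is smoothed,
#' drift-corrected and upward-rectified, diastoles (points of least
#' activation) are found with the comb, the trace is segmented into single
#' activations, and per-activation features are extracted. Activation and
#' recovery times are converted to global time and normalised to the clock
#' (the preceding boundary is subtracted), and every record is assigned to
#' the clock bin containing the segment's half-time; records whose
#' half-time falls before the first or after the last boundary are dropped
#' as potentially incomplete. Single-pixel failures never abort the map;
#' those positions stay NA.
#'
#' @inheritParams computeRecordingClock
#' @return A [FeatureMaps-class] with one bin per clock interval.
#' @export
analyzeMultiwave <- function(rec, periodFrames = NULL, comb = NULL,
                             params = traceParams()) {
    stopifnot(is(rec, "OMRecording"))
    comb <- resolveComb(periodFrames, comb, nFrames(rec))
    clock <- computeRecordingClock(rec, comb = comb, params = params)
    bounds <- clockBoundaries(clock)
    nBins <- length(bounds) - 1L
    dt <- frameInterval(rec)
    d <- intensityData(rec)
    dm <- dim(d)
    msk <- recordingMask(rec)
    perBeat <- emptyMaps(dm[1L], dm[2L], nBins)
    segParams <- params
    segParams$polarity <- "peaks"  # traces are rectified before segmentation
    nOverwritten <- 0L
    for (r in seq_len(dm[1L])) {
        for (c in seq_len(dm[2L])) {
            if (!is.null(msk) && !msk[r, c]) next
            tr <- smoothTrace(d[r, c, ], params$smoothingWindow,
                              params$smoothingOrder)
            if (params$driftPolyDegree >= 0L)
                tr <- subtractBaselineDrift(tr, params$driftPolyDegree)
            tr <- rectifyTrace(tr, params$polarity)
            res <- tryCatch({
                det <- combDetect(tr, comb, "troughs",
                                  params$refinementWidthMs, dt)
                diast <- toothPositions(det)
                ups <- if (params$objectSelection == "augmented")
                    detectUpstrokeTimes(tr, comb, "peaks",
                                        params$refinementWidthMs, dt)
                else NULL
                segs <- segmentActivations(tr, diast)
                for (s in segs) {
                    up <- NULL
                    if (!is.null(ups)) {
                        inSeg <- ups[ups >= s$startFrame &
                                     ups <= s$startFrame +
                                         length(s$values) - 1]
                        if (length(inSeg)) up <- inSeg[1L]
                    }
                    f <- extractFeatures(s, segParams, upstrokeTime = up,
                                         frameIntervalMs = dt)
                    if (!f$ok) next
                    nb <- normalizeToClock(f$halfTimeMs, clock)
                    if (is.na(nb$binIndex)) next
                    b <- nb$binIndex
                    actRel <- normalizeToClock(f$activationTimeMs, clock)
                    recRel <- normalizeToClock(f$recoveryTimeMs, clock)
                    if (!is.na(perBeat$amplitude[r, c, b]))
                        nOverwritten <- nOverwritten + 1L
                    perBeat$baseline[r, c, b] <- f$baseline
                    perBeat$amplitude[r, c, b] <- f$amplitude
                    perBeat$duration[r, c, b] <- f$durationMs
                    perBeat$recoveryTime[r, c, b] <- recRel$relativeTimeMs
                    perBeat$activationTime[r, c, b] <- actRel$relativeTimeMs
                }
                TRUE
            }, error = function(e) FALSE)
            invisible(res)
        }
    }
    if (nOverwritten > 0L)
        warning(nOverwritten, " activation(s) landed in an already ",
                "occupied clock bin and overwrote the earlier record")
    finishFeatureMaps(perBeat, dt, "multi", clock)
}

#' Single-wave analysis of a one-pass recording
#'
#' No clock and no comb: each pixel's whole trace is treated as one
#' activation, making no assumption on the rate of activation. Activation
#' and recovery times are global ms from the start of the recording.
#' For augmented object selection the upstroke is the steepest point of the
#' whole trace.
#'
#' @inheritParams computeRecordingClock
#' @return A [FeatureMaps-class] with a single bin.
#' @export
analyzeSinglewave <- function(rec, params = traceParams()) {
    stopifnot(is(rec, "OMRecording"))
    dt <- frameInterval(rec)
    d <- intensityData(rec)
    dm <- dim(d)
    msk <- recordingMask(rec)
    perBeat <- emptyMaps(dm[1L], dm[2L], 1L)
    segParams <- params
    segParams$polarity <- "peaks"
    for (r in seq_len(dm[1L])) {
        for (c in seq_len(dm[2L])) {
            if (!is.null(msk) && !msk[r, c]) next
            tr <- smoothTrace(d[r, c, ], params$smoothingWindow,
                              params$smoothingOrder)
            if (params$driftPolyDegree >= 0L)
                tr <- subtractBaselineDrift(tr, params$driftPolyDegree)
            tr <- rectifyTrace(tr, params$polarity)
            up <- if (params$objectSelection == "augmented")
                which.max(diff(tr)) else NULL
            f <- extractFeatures(tr, segParams, upstrokeTime = up,
                                 segmentStartGlobal = 1,
                                 frameIntervalMs = dt)
            if (!f$ok) next
            perBeat$baseline[r, c, 1L] <- f$baseline
            perBeat$amplitude[r, c, 1L] <- f$amplitude
            perBeat$duration[r, c, 1L] <- f$durationMs
            perBeat$recoveryTime[r, c, 1L] <- f$recoveryTimeMs
            perBeat$activationTime[r, c, 1L] <- f$activationTimeMs
        }
    }
    finishFeatureMaps(perBeat, dt, "single", NULL)
}

#' Average the beats of a regularly paced recording into one substack
#'
#' The recording is split into substacks one basic cycle length (BCL) long,
#' the first split point being the first recording-clock boundary and
#' further split points at multiples of the BCL after it; an incomplete
#' trailing substack is discarded. Because the splits are aligned to the
#' pacing, the substacks superimpose without further alignment and are
#' averaged frame-wise.
#'
#' @inheritParams computeRecordingClock
#' @param periodFrames the BCL in frames (user knowledge; not re-estimated
#'   from the clock).
#' @return A list with \code{recording} (the averaged [OMRecording-class],
#'   \code{periodFrames} frames long), \code{nSubstacks}, and
#'   \code{startFrame} (first split point).
#' @export
averageSubstacks <- function(rec, periodFrames, params = traceParams()) {
    stopifnot(is(rec, "OMRecording"))
    periodFrames <- as.integer(periodFrames)
    clock <- computeRecordingClock(rec, periodFrames = periodFrames,
                                   params = params)
    dt <- frameInterval(rec)
    t0 <- as.integer(round(clockBoundaries(clock)[1L] / dt)) + 1L
    n <- nFrames(rec)
    nSub <- (n - t0 + 1L) %/% periodFrames
    if (nSub < 2L)
        stop("fewer than 2 complete substacks after the first clock ",
             "boundary; cannot average")
    d <- intensityData(rec)
    acc <- array(0, dim = c(dim(d)[1L], dim(d)[2L], periodFrames))
    for (k in seq_len(nSub) - 1L) {
        i1 <- t0 + k * periodFrames
        acc <- acc + d[, , i1:(i1 + periodFrames - 1L), drop = FALSE]
    }
    avg <- acc / nSub
    list(recording = OMRecording(avg, dt, mask = recordingMask(rec)),
         nSubstacks = nSub, startFrame = t0)
}

#' Hybrid analysis: beat-average, then single-wave processing
#'
#' Substacks (one per wave pass, aligned by the recording clock) are
#' averaged with [averageSubstacks()] and the result is analysed with
#' [analyzeSinglewave()]. Averaging suppresses noise by roughly the square
#' root of the number of beats, which helps with severe noise or occasional
#' motion artefacts, but it discards per-beat temporal information: feature
#' changes over time -- alternans in particular -- are averaged away, so
#' use multi-wave analysis for those.
#'
#' @inheritParams averageSubstacks
#' @return A [FeatureMaps-class] (mode "hybrid", one bin).
#' @export
analyzeHybrid <- function(rec, periodFrames, params = traceParams()) {
    sub <- averageSubstacks(rec, periodFrames, params)
    maps <- analyzeSinglewave(sub$recording, params)
    maps@mode <- "hybrid"
    maps
}

#' Temporal standard deviation of a feature across wave passes
#'
#' The per-pixel sample standard deviation of a feature over the clock
#' bins. Where activation is regular the signal shape repeats and the SD is
#' low; where activation does not follow the comb's pattern segmentation
#' degrades and the SD is high, so this map flags sites of irregular
#' activation. Pixels with fewer than 2 assigned bins are NA.
#'
#' @param maps a multi-wave [FeatureMaps-class].
#' @param feature feature name (see [featureNames()]).
#' @return A numeric matrix.
#' @export
temporalSdMap <- function(maps, feature = "duration") {
    stopifnot(is(maps, "FeatureMaps"))
    a <- perBeatMaps(maps, feature)
    apply(a, c(1L, 2L), function(v) {
        v <- v[!is.na(v)]
        if (length(v) < 2L) NA_real_ else stats::sd(v)
    })
}

#' Estimate a custom comb from the spatial average trace (heuristic)
#'
#' For recordings whose activation pattern is not known a priori (e.g.
#' spontaneously beating cultures), the low-noise spatial average trace is
#' thresholded midway between its extremes, the signal maximum in each
#' above-threshold run is taken as an activation time, and the intervals
#' between those maxima define a custom comb. The comb can then drive the
#' per-pixel segmentation, where plain thresholding would fail at the much
#' lower pixel-level signal-to-noise. This is a convenience heuristic: it
#' assumes every beat rises above the midway threshold exactly once.
#'
#' @inheritParams computeRecordingClock
#' @param thresholdFraction position of the threshold between the trace
#'   minimum (0) and maximum (1); default 0.5.
#' @return A list with \code{comb} (a [Comb-class]) and \code{peakFrames}.
#' @export
estimateCustomComb <- function(rec, params = traceParams(),
                               thresholdFraction = 0.5) {
    stopifnot(is(rec, "OMRecording"))
    tr <- globalAverageTrace(rec, params)
    tr <- rectifyTrace(tr, params$polarity)
    thr <- min(tr) + thresholdFraction * (max(tr) - min(tr))
    above <- tr > thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep) < 2L)
        stop("fewer than 2 above-threshold activations in the average trace")
    peaks <- vapply(keep, function(i) {
        seg <- tr[starts[i]:ends[i]]
        starts[i] + which.max(seg) - 1L
    }, numeric(1))
    list(comb = customComb(diff(peaks)), peakFrames = peaks)
}
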