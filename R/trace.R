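#' Parameters controlling per-pixel trace analysis
#'
#' Bundles the tunable settings for smoothing, drift removal, segmentation
#' and feature extraction. Defaults follow common practice for rodent
#' optical-mapping traces sampled around 1 ms/frame: Savitzky-Golay window
#' 11 frames, order 4, and 4th-order polynomial drift removal.
#'
#' @param smoothingWindow odd Savitzky-Golay window in frames; 0 disables
#'   smoothing.
#' @param smoothingOrder polynomial order of the filter (< window).
#' @param driftPolyDegree degree of the polynomial fitted for baseline-drift
#'   removal; negative disables drift removal.
#' @param recoveryLevel fraction of recovery at which duration is measured,
#'   in (0,1): 0.8 gives APD80/CaTD80.
#' @param baselineMode \code{"first"}: baseline is the segment's first
#'   value; \code{"firstlast"}: mean of first and last values.
#' @param objectSelection how to pick among multiple above-threshold
#'   objects in one segment: \code{"first"}, \code{"largest"} (longest
#'   duration) or \code{"augmented"} (closest to the comb-detected upstroke).
#' @param polarity direction of the activation deflection: \code{"peaks"}
#'   (upward; calcium dyes) or \code{"troughs"} (downward; voltage dyes,
#'   where lower intensity means higher membrane potential).
#' @param refinementWidthMs local-search half-width for comb refinement, ms.
#' @return A list of class \code{"TraceParams"}.
#' @export
traceParams <- function(smoothingWindow = 11L, smoothingOrder = 4L,
                        driftPolyDegree = 4L, recoveryLevel = 0.8,
                        baselineMode = c("first", "firstlast"),
                        objectSelection = c("first", "largest", "augmented"),
                        polarity = c("peaks", "troughs"),
                        refinementWidthMs = 10) {
    baselineMode <- match.arg(baselineMode)
    objectSelection <- match.arg(objectSelection)
    polarity <- match.arg(polarity)
    smoothingWindow <- as.integer(smoothingWindow)
    if (smoothingWindow < 0L ||
        (smoothingWindow > 1L && smoothingWindow %% 2L == 0L))
        stop("'smoothingWindow' must be 0 (off) or an odd integer")
    if (smoothingWindow > 1L && smoothingOrder >= smoothingWindow)
        stop("'smoothingOrder' must be smaller than 'smoothingWindow'")
    if (!(recoveryLevel > 0 && recoveryLevel < 1))
        stop("'recoveryLevel' must lie strictly between 0 and 1 ",
             "(e.g. 0.8 for APD80)")
    if (refinementWidthMs < 0)
        stop("'refinementWidthMs' must be non-negative")
    structure(list(smoothingWindow = smoothingWindow,
                   smoothingOrder = as.integer(smoothingOrder),
                   driftPolyDegree = as.integer(driftPolyDegree),
                   recoveryLevel = recoveryLevel,
                   baselineMode = baselineMode,
                   objectSelection = objectSelection,
                   polarity = polarity,
                   refinementWidthMs = refinementWidthMs),
              class = "TraceParams")
}

#' Savitzky-Golay smoothing of a trace
#'
#' Least-squares local polynomial smoothing, chosen because it removes
#' noise while preserving genuine sharp deflections such as AP upstrokes.
#' Window 0 or 1 disables smoothing. Output length equals input length;
#' polynomials of degree at most \code{order} pass through unchanged.
#'
#' @param trace numeric vector.
#' @param window odd window length in frames (0/1 = identity).
#' @param order polynomial order, smaller than \code{window}.
#' @return The smoothed trace.
#' @export
smoothTrace <- function(trace, window = 11L, order = 4L) {
    trace <- as.numeric(trace)
    window <- as.integer(window)
    if (window <= 1L) return(trace)
    if (window %% 2L == 0L) stop("'window' must be odd")
    if (order >= window) stop("'order' must be smaller than 'window'")
    if (window > length(trace))
        stop("'window' exceeds the trace length")
    as.numeric(signal::sgolayfilt(trace, p = order, n = window))
}

#' Remove slow baseline drift while preserving the mean
#'
#' A least-squares polynomial of the given degree is fitted to the whole
#' trace over time and subtracted, and the mean of the original signal is
#' re-added. The output mean therefore equals the input mean exactly, so
#' the general offset of the recording is maintained -- e.g. photobleaching
#' can still be monitored as a drop in baseline across consecutive
#' recordings.
#'
#' @param trace numeric vector.
#' @param degree polynomial degree (>= 0); negative returns the trace
#'   unchanged.
#' @return The drift-corrected trace.
#' @export
subtractBaselineDrift <- function(trace, degree = 4L) {
    trace <- as.numeric(trace)
    degree <- as.integer(degree)
    if (degree < 0L) return(trace)
    n <- length(trace)
    if (n <= degree + 1L)
        stop("trace too short (", n, ") for a degree-", degree, " fit")
    if (degree == 0L) return(trace)  # fit is the mean; subtracting + re-adding
    tt <- seq_len(n)
    X <- cbind(1, stats::poly(tt, degree))
    fit <- stats::lm.fit(X, trace)
    trace - fit$fitted.values + mean(trace)
}

## Upward-rectify a trace: downward (voltage-style) deflections are analysed
## as 2*median - trace so every feature definition applies to upward signals.
rectifyTrace <- function(trace, polarity) {
    if (polarity == "troughs") 2 * stats::median(trace) - trace else trace
}

#' Split a trace into single activations at its diastoles
#'
#' @param trace numeric vector.
#' @param diastoles strictly increasing frame indices (1-based) inside the
#'   trace, at least 2. Segment k runs from diastole k to diastole k+1,
#'   inclusive of both endpoints.
#' @return List of segments; each has \code{values} and \code{startFrame}
#'   (global 1-based frame of its first sample).
#' @export
segmentActivations <- function(trace, diastoles) {
    trace <- as.numeric(trace)
    diastoles <- as.numeric(diastoles)
    if (length(diastoles) < 2L)
        stop("need at least 2 diastoles to form a segment")
    if (any(diff(diastoles) <= 0))
        stop("'diastoles' must be strictly increasing")
    if (diastoles[1L] < 1 || diastoles[length(diastoles)] > length(trace))
        stop("'diastoles' must lie within the trace")
    lapply(seq_len(length(diastoles) - 1L), function(k) {
        i1 <- diastoles[k]; i2 <- diastoles[k + 1L]
        list(values = trace[i1:i2], startFrame = i1)
    })
}

#' Segment objects above an intensity threshold
#'
#' Maximal runs of samples strictly above the threshold become objects.
#' Start and end times are linear interpolations of the threshold crossing
#' between the bracketing samples; a run touching the segment boundary uses
#' the boundary sample's time. Times are fractional frames relative to the
#' segment start (first sample = 0).
#'
#' @param segment numeric vector (one activation, upward deflection).
#' @param threshold intensity level.
#' @return data.frame with columns \code{start}, \code{end},
#'   \code{duration} (frames); zero rows when nothing exceeds the
#'   threshold.
#' @export
thresholdObjects <- function(segment, threshold) {
    segment <- as.numeric(segment)
    threshold <- unname(as.numeric(threshold))[1L]
    n <- length(segment)
    if (n < 2L) stop("segment needs at least 2 samples")
    above <- segment > threshold
    if (!any(above))
        return(data.frame(start = numeric(0), end = numeric(0),
                          duration = numeric(0)))
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    out <- lapply(keep, function(i) {
        i1 <- starts[i]; i2 <- ends[i]
        s <- if (i1 == 1L) 0 else {
            (i1 - 2) + (threshold - segment[i1 - 1L]) /
                (segment[i1] - segment[i1 - 1L])
        }
        e <- if (i2 == n) n - 1 else {
            (i2 - 1) + (segment[i2] - threshold) /
                (segment[i2] - segment[i2 + 1L])
        }
        c(start = s, end = e)
    })
    out <- do.call(rbind, out)
    data.frame(start = out[, "start"], end = out[, "end"],
               duration = out[, "end"] - out[, "start"])
}

#' Choose one segmented object per activation
#'
#' \code{"first"} takes the earliest object; \code{"largest"} the one with
#' the longest duration (ties: earliest); \code{"augmented"} the object
#' closest to the comb-detected upstroke time (distance 0 when the upstroke
#' lies inside the object, otherwise the gap to its nearest edge; ties:
#' earliest). Augmented selection is the most robust when noise or motion
#' artefacts split a transient into several objects.
#'
#' @param objects data.frame from [thresholdObjects()].
#' @param mode \code{"first"}, \code{"largest"} or \code{"augmented"}.
#' @param upstrokeTime fractional frame of the peak activation rate within
#'   the segment; required for \code{"augmented"}.
#' @return A single-row data.frame, or NULL when \code{objects} is empty
#'   (no activation found).
#' @export
selectObject <- function(objects, mode = c("first", "largest", "augmented"),
                         upstrokeTime = NULL) {
    mode <- match.arg(mode)
    if (is.null(objects) || nrow(objects) == 0L) return(NULL)
    objects <- objects[order(objects$start), , drop = FALSE]
    i <- switch(mode,
        first = 1L,
        largest = which.max(objects$duration),
        augmented = {
            if (is.null(upstrokeTime))
                stop("'augmented' selection requires 'upstrokeTime'")
            d <- pmax(0, pmax(objects$start - upstrokeTime,
                              upstrokeTime - objects$end))
            which.min(d)
        })
    objects[i, , drop = FALSE]
}

#' Extract the per-activation features from one segment
#'
#' Computes the five features of a single cardiac activation:
#' \itemize{
#'   \item baseline: the segment's first value, or the mean of first and
#'     last values (\code{baselineMode});
#'   \item amplitude: peak minus baseline;
#'   \item duration at the configured recovery level: the segment is
#'     thresholded at \code{baseline + (1 - recoveryLevel) * amplitude},
#'     one object is chosen by \code{objectSelection}, and the duration is
#'     the interpolated width of that object (so \code{recoveryLevel = 0.8}
#'     yields APD80/CaTD80);
#'   \item recovery time: the instant the recovery level is reached (the
#'     object's interpolated end);
#'   \item activation time: first interpolated up-crossing of half-maximal
#'     amplitude, searched within the selected object (widened to the whole
#'     segment if the object lies entirely above half-max, which can happen
#'     when \code{recoveryLevel < 0.5}).
#' }
#' Downward-deflection segments (\code{polarity = "troughs"}) are upward-
#' rectified about their median first, so amplitudes are always positive.
#' Times are returned in global ms (frame 1 = 0 ms). The half-time --
#' the temporal midpoint of the segment -- is returned for clock-bin
#' assignment.
#'
#' @param segment numeric vector, or a list with \code{values} and
#'   \code{startFrame} as produced by [segmentActivations()].
#' @param params a [traceParams()] object.
#' @param upstrokeTime optional upstroke time as a global fractional frame
#'   (required for augmented selection).
#' @param segmentStartGlobal 1-based global frame of the segment's first
#'   sample (ignored when \code{segment} carries \code{startFrame}).
#' @param frameIntervalMs milliseconds per frame.
#' @return A list with \code{ok} plus, when \code{ok} is TRUE:
#'   \code{baseline}, \code{amplitude}, \code{durationMs},
#'   \code{recoveryTimeMs}, \code{activationTimeMs}, \code{halfTimeMs}
#'   (all times global ms).
#' @export
extractFeatures <- function(segment, params = traceParams(),
                            upstrokeTime = NULL, segmentStartGlobal = 1,
                            frameIntervalMs = 1) {
    if (is.list(segment)) {
        segmentStartGlobal <- segment$startFrame
        segment <- segment$values
    }
    segment <- as.numeric(segment)
    n <- length(segment)
    miss <- list(ok = FALSE, baseline = NA_real_, amplitude = NA_real_,
                 durationMs = NA_real_, recoveryTimeMs = NA_real_,
                 activationTimeMs = NA_real_,
                 halfTimeMs = (segmentStartGlobal - 1 + (n - 1) / 2) *
                     frameIntervalMs)
    if (n < 2L) return(miss)
    seg <- rectifyTrace(segment, params$polarity)
    baseline <- switch(params$baselineMode,
        first = seg[1L],
        firstlast = (seg[1L] + seg[n]) / 2)
    amplitude <- max(seg) - baseline
    if (!is.finite(amplitude) || amplitude <= 0) return(miss)
    thr <- baseline + (1 - params$recoveryLevel) * amplitude
    objects <- thresholdObjects(seg, thr)
    upLocal <- if (is.null(upstrokeTime)) NULL else
        upstrokeTime - segmentStartGlobal
    obj <- selectObject(objects, params$objectSelection, upLocal)
    if (is.null(obj)) return(miss)
    halfThr <- baseline + 0.5 * amplitude
    act <- firstUpCrossing(seg, halfThr,
                           from = max(1L, floor(obj$start) + 1L),
                           to = min(n, ceiling(obj$end) + 1L))
    if (is.na(act))  # object entirely above half-max: widen to the segment
        act <- firstUpCrossing(seg, halfThr, from = 1L, to = n)
    if (is.na(act)) return(miss)
    g0 <- segmentStartGlobal - 1  # global time (frames) of local time 0
    list(ok = TRUE,
         baseline = baseline,
         amplitude = amplitude,
         durationMs = obj$duration * frameIntervalMs,
         recoveryTimeMs = (g0 + obj$end) * frameIntervalMs,
         activationTimeMs = (g0 + act) * frameIntervalMs,
         halfTimeMs = (g0 + (n - 1) / 2) * frameIntervalMs)
}

## First interpolated up-crossing of `level` between samples from..to
## (1-based); returns a fractional local time (sample 1 = time 0) or NA.
firstUpCrossing <- function(x, level, from = 1L, to = length(x)) {
    if (from >= to) return(NA_real_)
    for (j in from:(to - 1L)) {
        if (x[j] <= level && x[j + 1L] > level) {
            return((j - 1) + (level - x[j]) / (x[j + 1L] - x[j]))
        }
    }
    NA_real_
}

#' Normalize an event time to the recording clock
#'
#' The greatest clock boundary at or before the event is subtracted from
#' it, synchronising per-pixel event times onto the global per-beat bins.
#' Events before the first boundary or at/after the last one are
#' unassigned (both fields NA): they may belong to incomplete activations
#' at the edges of the recording.
#'
#' @param eventTimeMs event time(s) in global ms.
#' @param clock a [RecordingClock-class].
#' @return A data.frame with \code{relativeTimeMs} and \code{binIndex}
#'   (1-based bin = index of the preceding boundary), NA where unassigned.
#' @examples
#' clk <- recordingClock(c(426, 568, 710))  # boundaries at 497, 639 ms
#' normalizeToClock(568.79, clk)            # 71.79 ms into bin 1
#' @export
normalizeToClock <- function(eventTimeMs, clock) {
    stopifnot(is(clock, "RecordingClock"))
    b <- clockBoundaries(clock)
    idx <- findInterval(eventTimeMs, b)
    bad <- idx == 0L | eventTimeMs >= b[length(b)] | is.na(eventTimeMs)
    rel <- ifelse(bad, NA_real_, eventTimeMs - b[pmax(idx, 1L)])
    data.frame(relativeTimeMs = rel,
               binIndex = ifelse(bad, NA_integer_, idx))
}
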