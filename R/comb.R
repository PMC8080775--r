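#' Build a uniform comb for a regularly paced recording
#'
#' For pacing every \code{periodFrames} frames the comb has teeth the same
#' distance apart: offsets 0, p, 2p, ... The number of teeth is
#' \code{floor(nFrames / periodFrames)}, which maximises the beats covered
#' while leaving a full sliding range for the search.
#'
#' @param periodFrames pacing period in frames (>= 2).
#' @param nFrames length of the trace/recording the comb will be slid over
#'   (must fit at least 2 teeth).
#' @return A [Comb-class].
#' @examples
#' uniformComb(150, 1000)
#' @export
uniformComb <- function(periodFrames, nFrames) {
    periodFrames <- as.integer(periodFrames)
    nFrames <- as.integer(nFrames)
    if (is.na(periodFrames) || periodFrames < 2L)
        stop("'periodFrames' must be an integer >= 2")
    k <- nFrames %/% periodFrames
    if (k < 2L)
        stop("recording too short for 2 comb teeth at period ",
             periodFrames, " (", nFrames, " frames)")
    new("Comb", toothOffsets = (0:(k - 1L)) * periodFrames)
}

#' Build a custom comb from inter-beat intervals
#'
#' For activation patterns that are known but not uniform -- e.g. an S1-S2
#' protocol with three S1 stimuli 150 frames apart followed by an S2 coupled
#' at 60 frames, \code{customComb(c(150, 150, 60))} -- teeth are placed at
#' the cumulative sums of the intervals, prefixed with 0.
#'
#' @param intervalsFrames positive integer intervals between consecutive
#'   teeth.
#' @return A [Comb-class].
#' @examples
#' toothOffsets(customComb(c(150, 150, 60)))  # 0 150 300 360
#' @export
customComb <- function(intervalsFrames) {
    intervalsFrames <- as.integer(intervalsFrames)
    if (length(intervalsFrames) == 0L)
        stop("'intervalsFrames' must not be empty")
    if (anyNA(intervalsFrames) || any(intervalsFrames < 1L))
        stop("all intervals must be positive integers")
    new("Comb", toothOffsets = c(0L, cumsum(intervalsFrames)))
}

#' Locate one extremum per expected beat with the comb algorithm
#'
#' The comb is slid over the trace, measuring the mean signal under its
#' teeth at every placement that fits fully inside the trace (shifts
#' 0 .. N - span - 1). The placement with the lowest mean is selected for
#' \code{polarity = "troughs"} (highest for \code{"peaks"}); ties go to the
#' smallest shift. A local search within \code{refinementWidthMs} of each
#' tooth (clipped at the trace bounds) then refines each position to the
#' nearest extremum, ties going to the earliest index. Refined positions are
#' kept strictly increasing: each tooth's search window is clipped to start
#' after the previous refined tooth, so a refinement can never reorder the
#' detections (downstream segmentation needs ordered diastoles). Because the teeth
#' move as one rigid body, detected extrema are guaranteed to be spaced
#' according to the known activation pattern (up to the refinement width),
#' which makes the method robust to noise and to the spacing artefacts of
#' threshold-based detectors.
#'
#' @param trace numeric vector.
#' @param comb a [Comb-class]; its span must be smaller than the trace.
#' @param polarity \code{"troughs"} to find minima (diastoles,
#'   voltage-style downward deflections) or \code{"peaks"} for maxima
#'   (calcium-style).
#' @param refinementWidthMs half-width of the local search, in ms
#'   (default 10; rounded to whole frames).
#' @param frameIntervalMs milliseconds per frame (default 1).
#' @return A [CombDetection-class].
#' @examples
#' tr <- rep(c(1, 0, 1, 1), 3)
#' combDetect(tr, uniformComb(4, 12), "troughs", refinementWidthMs = 0)
#' @export
combDetect <- function(trace, comb, polarity = c("troughs", "peaks"),
                       refinementWidthMs = 10, frameIntervalMs = 1) {
    polarity <- match.arg(polarity)
    stopifnot(is(comb, "Comb"))
    trace <- as.numeric(trace)
    n <- length(trace)
    span <- combSpan(comb)
    if (span >= n)
        stop("comb span (", span, ") must be smaller than the trace (",
             n, " frames)")
    off <- toothOffsets(comb)
    shifts <- 0:(n - span - 1L)
    idx <- outer(shifts, off + 1L, "+")
    obj <- rowMeans(matrix(trace[idx], nrow = length(shifts)))
    best <- if (polarity == "troughs") which.min(obj) else which.max(obj)
    bestShift <- shifts[best]
    w <- as.integer(round(refinementWidthMs / frameIntervalMs))
    if (w < 0L) stop("'refinementWidthMs' must be non-negative")
    pos0 <- bestShift + off + 1L
    pos <- pos0
    prev <- 0L
    for (k in seq_along(pos0)) {
        ## search window clipped to the trace and to strictly after the
        ## previous tooth, so refinement cannot break monotonicity
        lo <- max(1L, pos0[k] - w, prev + 1L)
        hi <- min(n, pos0[k] + w)
        if (lo > hi) {
            pos[k] <- max(pos0[k], prev + 1L)  # degenerate width: unrefined
        } else {
            win <- trace[lo:hi]
            j <- if (polarity == "troughs") which.min(win) else
                which.max(win)
            pos[k] <- lo + j - 1L
        }
        prev <- pos[k]
    }
    new("CombDetection", bestOffset = as.integer(bestShift),
        toothPositions = as.numeric(pos), objective = obj[best])
}

#' Detect upstroke times (peak activation rate) with the comb
#'
#' The discrete derivative \code{d[t] = trace[t+1] - trace[t]} of the whole
#' (smoothed) trace is formed and the comb algorithm is applied to it to
#' find the time of steepest deflection in every beat: derivative maxima
#' when the activation deflects upward (calcium-style, \code{polarity =
#' "peaks"}), derivative minima when it deflects downward (voltage-style,
#' \code{"troughs"}). Working on the whole trace makes this far more robust
#' to noise than locating the steepest point inside a single beat.
#'
#' @inheritParams combDetect
#' @param polarity direction of the activation deflection in the signal:
#'   \code{"peaks"} (upward) or \code{"troughs"} (downward).
#' @return Numeric vector of upstroke frames (index of the sample at the
#'   start of the steepest step), one per tooth.
#' @export
detectUpstrokeTimes <- function(trace, comb, polarity = c("peaks", "troughs"),
                                refinementWidthMs = 10, frameIntervalMs = 1) {
    polarity <- match.arg(polarity)
    trace <- as.numeric(trace)
    if (length(trace) < combSpan(comb) + 2L)
        stop("trace too short for the comb's span plus a derivative sample")
    d <- diff(trace)
    det <- combDetect(d, comb, polarity = polarity,
                      refinementWidthMs = refinementWidthMs,
                      frameIntervalMs = frameIntervalMs)
    toothPositions(det)
}
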