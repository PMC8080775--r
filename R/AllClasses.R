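#' @import methods
NULL

#' OMRecording: an optical-mapping recording
#'
#' Container for a fluorescence intensity movie: a 3-D array indexed
#' \code{[row, col, frame]}, the frame interval in milliseconds, and an
#' optional logical mask selecting the pixels to analyse (TRUE = analysed).
#' Intensity values are stored as doubles in arbitrary units; the mask is
#' carried alongside the data rather than applied destructively, so raw
#' intensities are always preserved.
#'
#' @slot data numeric 3-D array, \code{[row, col, frame]}.
#' @slot frameIntervalMs positive scalar, milliseconds per frame.
#'   Supplied by the user; file metadata is never consulted.
#' @slot mask \code{NULL} or a logical matrix with the spatial shape of
#'   \code{data}.
#'
#' @seealso [readTifStack()], [readImageFolder()], [spatialBin()],
#'   [applyMask()]
#' @export
setClass("OMRecording",
    slots = c(data = "array", frameIntervalMs = "numeric", mask = "ANY"))

setValidity("OMRecording", function(object) {
    d <- object@data
    msg <- character(0)
    if (length(dim(d)) != 3L)
        msg <- c(msg, "'data' must be a 3-D array [row, col, frame]")
    else {
        if (dim(d)[1L] < 1L || dim(d)[2L] < 1L)
            msg <- c(msg, "'data' needs at least 1 row and 1 column")
        if (dim(d)[3L] < 2L)
            msg <- c(msg, "'data' needs at least 2 frames")
    }
    if (!is.numeric(d))
        msg <- c(msg, "'data' must be numeric")
    fi <- object@frameIntervalMs
    if (length(fi) != 1L || !is.finite(fi) || fi <= 0)
        msg <- c(msg, "'frameIntervalMs' must be a positive scalar")
    m <- object@mask
    if (!is.null(m)) {
        if (!is.logical(m) || !is.matrix(m))
            msg <- c(msg, "'mask' must be NULL or a logical matrix")
        else if (length(dim(d)) == 3L &&
                 !identical(dim(m), dim(d)[1:2]))
            msg <- c(msg, "'mask' shape must match the spatial shape of 'data'")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an OMRecording
#'
#' @param data numeric 3-D array \code{[row, col, frame]}; coerced to double.
#' @param frameIntervalMs milliseconds per frame (positive scalar).
#' @param mask optional logical matrix (rows x cols), TRUE = pixel analysed.
#' @return An [OMRecording-class] object.
#' @examples
#' rec <- OMRecording(array(rnorm(4 * 4 * 10), c(4, 4, 10)), 2)
#' dim(intensityData(rec))
#' @export
OMRecording <- function(data, frameIntervalMs, mask = NULL) {
    storage.mode(data) <- "double"
    new("OMRecording", data = data,
        frameIntervalMs = as.numeric(frameIntervalMs), mask = mask)
}

#' Comb: tooth offsets encoding a known activation pattern
#'
#' A comb is an ordered set of tooth offsets (in frames, first offset 0) that
#' encodes where successive beats are expected relative to one another. A
#' uniform comb with period p has teeth at 0, p, 2p, ...; a custom comb takes
#' arbitrary inter-tooth intervals (e.g. for S1-S2 protocols).
#'
#' @slot toothOffsets strictly increasing integer vector, first element 0.
#' @seealso [uniformComb()], [customComb()], [combDetect()]
#' @export
setClass("Comb", slots = c(toothOffsets = "integer"))

setValidity("Comb", function(object) {
    off <- object@toothOffsets
    msg <- character(0)
    if (length(off) < 1L)
        msg <- c(msg, "a comb needs at least one tooth")
    else {
        if (off[1L] != 0L)
            msg <- c(msg, "first tooth offset must be 0")
        if (length(off) > 1L && any(diff(off) <= 0L))
            msg <- c(msg, "tooth offsets must be strictly increasing")
    }
    if (length(msg)) msg else TRUE
})

#' CombDetection: result of positioning a comb on a trace
#'
#' @slot bestOffset integer shift (frames, 0-based) of the comb from the
#'   start of the trace that optimises the mean signal under the teeth.
#' @slot toothPositions integer frame indices (1-based) of the refined
#'   extremum found for each tooth; strictly increasing.
#' @slot objective mean signal under the teeth at \code{bestOffset}.
#' @export
setClass("CombDetection",
    slots = c(bestOffset = "integer", toothPositions = "numeric",
              objective = "numeric"))

setValidity("CombDetection", function(object) {
    p <- object@toothPositions
    if (length(p) > 1L && any(diff(p) <= 0))
        "tooth positions must be strictly increasing" else TRUE
})

#' RecordingClock: global per-beat bin boundaries
#'
#' The recording clock is the set of midpoints between consecutive peak
#' activations of the spatially averaged trace, in milliseconds from the
#' first frame (frame 1 = 0 ms). The clock does not segment single beats
#' well; its purpose is to provide a consistent set of global bins so that
#' features extracted from different pixels (whose own diastoles differ) can
#' be assigned to the same wave pass and synchronised for mapping.
#'
#' @slot boundariesMs strictly increasing numeric, bin boundaries in ms.
#' @slot peakTimesMs the peak-activation times (ms) the boundaries derive
#'   from; boundaries are consecutive midpoints, so there is one fewer
#'   boundary than peaks.
#' @seealso [computeRecordingClock()], [normalizeToClock()]
#' @export
setClass("RecordingClock",
    slots = c(boundariesMs = "numeric", peakTimesMs = "numeric"))

setValidity("RecordingClock", function(object) {
    b <- object@boundariesMs
    p <- object@peakTimesMs
    msg <- character(0)
    if (length(b) < 2L)
        msg <- c(msg, "a clock needs at least 2 boundaries (>= 3 peaks)")
    if (length(b) > 1L && any(diff(b) <= 0))
        msg <- c(msg, "boundaries must be strictly increasing")
    if (length(p) && length(b) != length(p) - 1L)
        msg <- c(msg, "need length(boundaries) == length(peakTimes) - 1")
    if (length(p) > 1L && length(b) == length(p) - 1L &&
        any(abs(b - (p[-length(p)] + p[-1L]) / 2) > 1e-6))
        msg <- c(msg, "boundaries must be midpoints between peak times")
    if (length(msg)) msg else TRUE
})

#' Construct a RecordingClock from peak-activation times
#'
#' @param peakTimesMs strictly increasing peak-activation times in ms
#'   (at least 3).
#' @return A [RecordingClock-class] with boundaries at consecutive midpoints.
#' @examples
#' recordingClock(c(426, 568, 710))
#' @export
recordingClock <- function(peakTimesMs) {
    peakTimesMs <- as.numeric(peakTimesMs)
    if (length(peakTimesMs) < 3L)
        stop("need at least 3 peak activations to build a recording clock")
    b <- (peakTimesMs[-length(peakTimesMs)] + peakTimesMs[-1L]) / 2
    new("RecordingClock", boundariesMs = b, peakTimesMs = peakTimesMs)
}

#' FeatureMaps: per-beat and averaged spatial feature maps
#'
#' Holds, for each extracted feature (baseline, amplitude, duration,
#' recoveryTime, activationTime), a dense per-beat stack \code{[row, col,
#' bin]} with NA marking missing values, the beat-averaged 2-D map, the
#' spatial mean per beat, and a scalar grand mean. Durations and times are
#' in ms; baseline and amplitude in the recording's intensity units.
#' In multi-wave mode activation and recovery times are relative to the
#' recording clock; in single-wave/hybrid mode they are global times from
#' frame 1 = 0 ms.
#'
#' @slot perBeat named list of 3-D arrays \code{[row, col, bin]}.
#' @slot beatMean named list of matrices (mean over bins, NA ignored).
#' @slot spatialMeanPerBeat named list of per-bin spatial means.
#' @slot grandMean named numeric vector of overall means.
#' @slot frameIntervalMs frame interval of the source recording.
#' @slot mode one of "multi", "single", "hybrid".
#' @slot clock the [RecordingClock-class] used (or NULL).
#' @export
setClass("FeatureMaps",
    slots = c(perBeat = "list", beatMean = "list",
              spatialMeanPerBeat = "list", grandMean = "numeric",
              frameIntervalMs = "numeric", mode = "character",
              clock = "ANY"))

#' VelocityField: local conduction-velocity vector field
#'
#' Per-pixel conduction velocity from a local polynomial fit of the
#' activation surface: velocity components, speed, and a validity mask for
#' pixels where the fit succeeded and the gradient was non-degenerate.
#' Units are mm/ms when activation times are in ms and pitch in mm.
#'
#' @slot vx,vy numeric matrices of velocity components.
#' @slot speed numeric matrix, \code{sqrt(vx^2 + vy^2)}.
#' @slot valid logical matrix.
#' @seealso [baylyLocalCv()]
#' @export
setClass("VelocityField",
    slots = c(vx = "matrix", vy = "matrix", speed = "matrix",
              valid = "matrix"))

#' AlternansMap: beat-to-beat alternation of a mapped feature
#'
#' Even-pass and odd-pass bin maps are averaged separately; per pixel the
#' alternans magnitude is reported as the large-to-small ratio
#' \code{max(e,o)/min(e,o)}, the symmetric ratio \code{|e-o|/(e+o)} (sMAPE)
#' or \code{1 - min(e,o)/max(e,o)}.
#'
#' @slot metric one of "largeToSmall", "smape", "oneMinusRatio".
#' @slot values numeric matrix of the metric.
#' @slot mapEven,mapOdd mean feature maps over even / odd wave passes.
#' @slot sourceFeature name of the feature the map derives from.
#' @seealso [alternansMap()]
#' @export
setClass("AlternansMap",
    slots = c(metric = "character", values = "matrix",
              mapEven = "matrix", mapOdd = "matrix",
              sourceFeature = "character"))
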