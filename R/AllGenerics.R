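#' @include AllClasses.R
NULL

#' Accessors for opticomb S4 classes
#'
#' @param x an opticomb object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensityData", function(x) standardGeneric("intensityData"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("recordingMask", function(x) standardGeneric("recordingMask"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("toothOffsets", function(x) standardGeneric("toothOffsets"))

#' @rdname accessors
#' @export
setGeneric("combSpan", function(x) standardGeneric("combSpan"))

#' @rdname accessors
#' @export
setGeneric("nTeeth", function(x) standardGeneric("nTeeth"))

#' @rdname accessors
#' @export
setGeneric("bestOffset", function(x) standardGeneric("bestOffset"))

#' @rdname accessors
#' @export
setGeneric("toothPositions", function(x) standardGeneric("toothPositions"))

#' @rdname accessors
#' @export
setGeneric("clockBoundaries", function(x) standardGeneric("clockBoundaries"))

#' @rdname accessors
#' @export
setGeneric("peakTimes", function(x) standardGeneric("peakTimes"))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' Extract per-beat map stack for one feature
#' @param x a [FeatureMaps-class].
#' @param feature feature name (see [featureNames()]).
#' @export
setGeneric("perBeatMaps", function(x, feature) standardGeneric("perBeatMaps"))

#' Extract the beat-averaged map for one feature
#' @param x a [FeatureMaps-class].
#' @param feature feature name (see [featureNames()]).
#' @export
setGeneric("beatMeanMap", function(x, feature) standardGeneric("beatMeanMap"))

## ---- OMRecording ----

#' @rdname accessors
#' @export
setMethod("intensityData", "OMRecording", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("frameInterval", "OMRecording", function(x) x@frameIntervalMs)

#' @rdname accessors
#' @export
setMethod("recordingMask", "OMRecording", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("nFrames", "OMRecording", function(x) dim(x@data)[3L])

setMethod("dim", "OMRecording", function(x) dim(x@data))

setMethod("show", "OMRecording", function(object) {
    d <- dim(object@data)
    cat(sprintf("OMRecording: %d x %d pixels, %d frames @ %g ms/frame\n",
                d[1L], d[2L], d[3L], object@frameIntervalMs))
    if (!is.null(object@mask))
        cat(sprintf("  mask: %d of %d pixels analysed\n",
                    sum(object@mask), length(object@mask)))
    cat(sprintf("  intensity range: [%g, %g]\n",
                min(object@data), max(object@data)))
})

## ---- Comb ----

#' @rdname accessors
#' @export
setMethod("toothOffsets", "Comb", function(x) x@toothOffsets)

#' @rdname accessors
#' @export
setMethod("combSpan", "Comb",
    function(x) x@toothOffsets[length(x@toothOffsets)])

#' @rdname accessors
#' @export
setMethod("nTeeth", "Comb", function(x) length(x@toothOffsets))

setMethod("show", "Comb", function(object) {
    off <- object@toothOffsets
    cat(sprintf("Comb: %d teeth, span %d frames\n", length(off),
                off[length(off)]))
    cat("  offsets:", paste(utils::head(off, 8L), collapse = ", "),
        if (length(off) > 8L) "..." else "", "\n")
})

## ---- CombDetection ----

#' @rdname accessors
#' @export
setMethod("bestOffset", "CombDetection", function(x) x@bestOffset)

#' @rdname accessors
#' @export
setMethod("toothPositions", "CombDetection", function(x) x@toothPositions)

setMethod("show", "CombDetection", function(object) {
    cat(sprintf("CombDetection: offset %d, objective %g\n",
                object@bestOffset, object@objective))
    cat("  positions:",
        paste(utils::head(object@toothPositions, 8L), collapse = ", "),
        if (length(object@toothPositions) > 8L) "..." else "", "\n")
})

## ---- RecordingClock ----

#' @rdname accessors
#' @export
setMethod("clockBoundaries", "RecordingClock", function(x) x@boundariesMs)

#' @rdname accessors
#' @export
setMethod("peakTimes", "RecordingClock", function(x) x@peakTimesMs)

setMethod("length", "RecordingClock", function(x) length(x@boundariesMs))

setMethod("show", "RecordingClock", function(object) {
    b <- object@boundariesMs
    cat(sprintf("RecordingClock: %d boundaries (%d bins), %g .. %g ms\n",
                length(b), length(b) - 1L, b[1L], b[length(b)]))
})

## ---- FeatureMaps ----

#' @rdname accessors
#' @export
setMethod("featureNames", "FeatureMaps", function(x) names(x@perBeat))

#' @describeIn perBeatMaps method for FeatureMaps
#' @export
setMethod("perBeatMaps", "FeatureMaps", function(x, feature) {
    feature <- match.arg(feature, names(x@perBeat))
    x@perBeat[[feature]]
})

#' @describeIn beatMeanMap method for FeatureMaps
#' @export
setMethod("beatMeanMap", "FeatureMaps", function(x, feature) {
    feature <- match.arg(feature, names(x@beatMean))
    x@beatMean[[feature]]
})

setMethod("show", "FeatureMaps", function(object) {
    d <- dim(object@perBeat[[1L]])
    cat(sprintf("FeatureMaps (%s mode): %d x %d pixels, %d bin(s)\n",
                object@mode, d[1L], d[2L], d[3L]))
    gm <- object@grandMean
    cat("  grand means:\n")
    for (f in names(gm))
        cat(sprintf("    %-15s %s\n", f,
                    ifelse(is.na(gm[[f]]), "NA", format(gm[[f]]))))
})

## ---- VelocityField ----

setMethod("show", "VelocityField", function(object) {
    v <- object@speed[object@valid]
    cat(sprintf("VelocityField: %d x %d pixels, %d valid\n",
                nrow(object@speed), ncol(object@speed), sum(object@valid)))
    if (length(v))
        cat(sprintf("  speed: median %g, IQR [%g, %g]\n",
                    stats::median(v), stats::quantile(v, 0.25),
                    stats::quantile(v, 0.75)))
})

#' @rdname velocityAccessors
#' @export
velocityComponents <- function(x) {
    stopifnot(is(x, "VelocityField"))
    list(vx = x@vx, vy = x@vy)
}

#' Velocity field accessors
#'
#' @param x a [VelocityField-class].
#' @return \code{velocityComponents}: list with \code{vx}, \code{vy};
#'   \code{velocitySpeed}: matrix of speeds (NA where invalid);
#'   \code{velocityValid}: logical matrix.
#' @name velocityAccessors
#' @export
velocitySpeed <- function(x) {
    stopifnot(is(x, "VelocityField"))
    out <- x@speed
    out[!x@valid] <- NA_real_
    out
}

#' @rdname velocityAccessors
#' @export
velocityValid <- function(x) {
    stopifnot(is(x, "VelocityField"))
    x@valid
}

## ---- AlternansMap ----

setMethod("show", "AlternansMap", function(object) {
    v <- object@values[!is.na(object@values)]
    cat(sprintf("AlternansMap (%s of %s): %d x %d pixels, %d defined\n",
                object@metric, object@sourceFeature,
                nrow(object@values), ncol(object@values), length(v)))
    if (length(v))
        cat(sprintf("  values: median %g, max %g\n", stats::median(v),
                    max(v)))
})

#' Alternans map accessors
#'
#' @param x an [AlternansMap-class].
#' @return \code{alternansValues}: matrix of the metric;
#'   \code{alternansEvenOdd}: list with the even-pass and odd-pass mean maps.
#' @name alternansAccessors
#' @export
alternansValues <- function(x) {
    stopifnot(is(x, "AlternansMap"))
    x@values
}

#' @rdname alternansAccessors
#' @export
alternansEvenOdd <- function(x) {
    stopifnot(is(x, "AlternansMap"))
    list(even = x@mapEven, odd = x@mapOdd)
}
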