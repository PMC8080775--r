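#' Read a multi-slice TIFF stack as a recording
#'
#' Each TIFF slice becomes one frame. 8/16-bit unsigned samples are read as
#' their raw integer values; 32-bit float samples are read as stored. All
#' values are converted to double. The frame interval is user knowledge and
#' must be supplied; TIFF metadata is ignored.
#'
#' @param path path to a multi-slice TIFF file (at least 2 slices, all the
#'   same shape).
#' @param frameIntervalMs milliseconds per frame.
#' @return An [OMRecording-class].
#' @examples
#' rec <- makePlanarWaveStack(rows = 6, cols = 6, speedPxPerFrame = 1,
#'     bclFrames = 40, nBeats = 3)$recording
#' f <- tempfile(fileext = ".tif")
#' writeTifStack(rec, f)
#' rec2 <- readTifStack(f, frameIntervalMs = 1)
#' @export
readTifStack <- function(path, frameIntervalMs) {
    if (!file.exists(path))
        stop("cannot read TIFF stack: file not found: ", path)
    info <- tryCatch(tiff::readTIFF(path, payload = FALSE),
                     error = function(e)
                         stop("corrupt or unreadable TIFF: ", path,
                              " (", conditionMessage(e), ")"))
    ## 8/16-bit samples are integers: read raw values; 32-bit samples are
    ## IEEE floats: read as stored (as.is would reinterpret the bits)
    asIs <- all(info$bits.per.sample < 32L)
    slices <- tiff::readTIFF(path, all = TRUE, as.is = asIs)
    if (!is.list(slices)) slices <- list(slices)
    stackFromFrames(slices, frameIntervalMs, what = path)
}

#' Read a folder of image frames as a recording
#'
#' Frames are ordered by lexicographic filename sort (zero-padded names
#' recommended), never by file dates. TIF and PNG frames are supported; all
#' frames must share one extension and one shape. Integer samples are
#' restored to their native range (e.g. an 8-bit PNG yields values 0..255).
#'
#' @inheritParams readTifStack
#' @param path folder containing at least 2 frames of one supported
#'   extension.
#' @return An [OMRecording-class].
#' @export
readImageFolder <- function(path, frameIntervalMs) {
    if (!dir.exists(path))
        stop("cannot read image folder: not a directory: ", path)
    exts <- c(tif = "\\.tiff?$", png = "\\.png$", jpg = "\\.jpe?g$")
    files <- lapply(exts, function(p)
        list.files(path, pattern = p, ignore.case = TRUE))
    nper <- lengths(files)
    if (sum(nper > 0L) > 1L)
        stop("image folder mixes extensions; use a single format")
    if (all(nper == 0L))
        stop("no TIF/PNG frames found in ", path)
    kind <- names(which(nper > 0L))
    if (kind == "jpg")
        stop("JPEG frame folders are not supported; convert to PNG or TIF")
    fnames <- sort(files[[kind]], method = "radix")
    if (length(fnames) < 2L)
        stop("need at least 2 frames, found ", length(fnames))
    frames <- lapply(file.path(path, fnames), function(f) {
        if (kind == "tif") {
            tiff::readTIFF(f, as.is = TRUE)
        } else {
            img <- png::readPNG(f, info = TRUE)
            info <- attr(img, "info")
            depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
            img * (2^depth - 1)
        }
    })
    frames <- lapply(frames, function(fr) {
        if (length(dim(fr)) == 3L) fr[, , 1L] else fr  # first channel
    })
    stackFromFrames(frames, frameIntervalMs, what = path)
}

## Assemble a list of equally shaped matrices into an OMRecording.
stackFromFrames <- function(frames, frameIntervalMs, what = "input") {
    if (length(frames) < 2L)
        stop("recording needs at least 2 frames, got ", length(frames),
             " in ", what)
    shp <- dim(frames[[1L]])
    if (is.null(shp)) shp <- c(1L, length(frames[[1L]]))
    same <- vapply(frames, function(f) {
        d <- dim(f); if (is.null(d)) d <- c(1L, length(f))
        identical(as.integer(d), as.integer(shp))
    }, logical(1))
    if (!all(same))
        stop("inconsistent frame shapes in ", what)
    arr <- array(0, dim = c(shp[1L], shp[2L], length(frames)))
    for (k in seq_along(frames)) arr[, , k] <- frames[[k]]
    OMRecording(arr, frameIntervalMs)
}

#' Write a recording as a multi-slice TIFF stack
#'
#' Values are stored as 16-bit unsigned integers after rounding (optionally
#' scaled first), so stacks whose values are integers in 0..65535 round-trip
#' exactly through [readTifStack()].
#'
#' @param rec an [OMRecording-class].
#' @param path output file path.
#' @param scale multiplier applied before rounding (default 1).
#' @return \code{path}, invisibly.
#' @export
writeTifStack <- function(rec, path, scale = 1) {
    stopifnot(is(rec, "OMRecording"))
    d <- intensityData(rec)
    v <- round(d * scale)
    if (any(v < 0) || any(v > 65535))
        stop("scaled values fall outside the 16-bit range 0..65535")
    slices <- lapply(seq_len(dim(d)[3L]),
                     function(k) v[, , k, drop = TRUE] / 65535)
    slices <- lapply(slices, function(s) {
        if (is.null(dim(s))) matrix(s, nrow = dim(d)[1L]) else s
    })
    tiff::writeTIFF(slices, path, bits.per.sample = 16L)
    invisible(path)
}

#' Spatially bin a recording
#'
#' Each output pixel's trace is the arithmetic mean of a \code{factor x
#' factor} block of input traces. Trailing rows/columns that do not fill a
#' complete block are discarded; the frame count is unchanged. Any mask is
#' binned with the same rule: an output pixel is analysed only when every
#' pixel of its block is.
#'
#' @param rec an [OMRecording-class].
#' @param factor positive integer block edge (1 = no binning).
#' @return A binned [OMRecording-class].
#' @export
spatialBin <- function(rec, factor) {
    stopifnot(is(rec, "OMRecording"))
    factor <- as.integer(factor)
    if (is.na(factor) || factor < 1L)
        stop("'factor' must be a positive integer")
    d <- dim(rec@data)
    if (factor > d[1L] || factor > d[2L])
        stop("'factor' exceeds a spatial dimension of the recording")
    if (factor == 1L) return(rec)
    nr <- d[1L] %/% factor
    nc <- d[2L] %/% factor
    x <- rec@data[seq_len(nr * factor), seq_len(nc * factor), , drop = FALSE]
    ## average factor x factor blocks: collapse rows, then columns
    dim(x) <- c(factor, nr, nc * factor * d[3L])
    x <- colMeans(x)
    dim(x) <- c(nr, factor, nc, d[3L])
    x <- apply(x, c(1L, 3L, 4L), mean)
    mask <- rec@mask
    if (!is.null(mask)) {
        m <- mask[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
        dim(m) <- c(factor, nr, nc * factor)
        m <- colSums(m) == factor
        dim(m) <- c(nr, factor, nc)
        m <- apply(m, c(1L, 3L), all)
    }
    OMRecording(x, rec@frameIntervalMs, mask = if (is.null(mask)) NULL else m)
}

#' Attach a binary analysis mask to a recording
#'
#' The mask is carried with the recording, not applied to the intensities:
#' downstream per-pixel analyses skip FALSE pixels and write NA at their
#' positions in every output map.
#'
#' @param rec an [OMRecording-class].
#' @param mask logical matrix with the recording's spatial shape
#'   (TRUE = analyse).
#' @return The recording with the mask attached.
#' @export
applyMask <- function(rec, mask) {
    stopifnot(is(rec, "OMRecording"))
    if (is.numeric(mask)) {
        mode(mask) <- "logical"
    }
    if (!is.matrix(mask) || !is.logical(mask) ||
        !identical(dim(mask), dim(rec@data)[1:2]))
        stop("'mask' must be a logical matrix matching the recording's ",
             "spatial shape")
    rec@mask <- mask
    validObject(rec)
    rec
}

#' Read a mask image (PNG or TIFF)
#'
#' Pixels with value above half the image range become TRUE.
#'
#' @param path path to a single-frame PNG or TIFF image.
#' @return A logical matrix.
#' @export
readMaskImage <- function(path) {
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
        img <- png::readPNG(path)
    } else {
        img <- tiff::readTIFF(path)
    }
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img > (min(img) + max(img)) / 2
}

#' Maximum-contrast image of a recording
#'
#' Per-pixel contrast score: the max-over-time minus min-over-time of the
#' (optionally lightly smoothed) trace, linearly rescaled to span [0, 1]
#' over analysed pixels. Intended as a guide for drawing analysis masks:
#' pixels carrying signal light up, background stays dark. The max - min
#' definition is this package's choice of contrast score.
#'
#' @param rec an [OMRecording-class].
#' @param smoothingWindow odd Savitzky-Golay window applied to each trace
#'   before taking the range; 0 (default) disables smoothing.
#' @param smoothingOrder polynomial order for the smoothing.
#' @return A numeric matrix in [0, 1]; masked pixels are NA. If all
#'   contrasts are equal (e.g. a temporally constant stack) the rescaling is
#'   degenerate and the image is all zeros.
#' @export
maxContrastImage <- function(rec, smoothingWindow = 0L, smoothingOrder = 2L) {
    stopifnot(is(rec, "OMRecording"))
    d <- dim(rec@data)
    out <- matrix(NA_real_, d[1L], d[2L])
    for (r in seq_len(d[1L])) {
        for (c in seq_len(d[2L])) {
            if (!is.null(rec@mask) && !rec@mask[r, c]) next
            tr <- rec@data[r, c, ]
            if (smoothingWindow > 1L)
                tr <- smoothTrace(tr, smoothingWindow, smoothingOrder)
            out[r, c] <- max(tr) - min(tr)
        }
    }
    rng <- range(out, na.rm = TRUE)
    if (diff(rng) == 0) {
        out[!is.na(out)] <- 0
    } else {
        out <- (out - rng[1L]) / diff(rng)
    }
    out
}

#' Write a 2-D map as CSV
#'
#' One CSV row per image row; missing values (NA) become empty cells.
#'
#' @param map numeric matrix (NA = missing).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMapCsv <- function(map, path) {
    stopifnot(is.matrix(map))
    utils::write.table(map, path, sep = ",", na = "", row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}

#' Read a 2-D map written by [writeMapCsv()]
#'
#' @param path CSV path.
#' @return Numeric matrix with NA for empty cells.
#' @export
readMapCsv <- function(path) {
    as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                na.strings = c("NA", "")))
}
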