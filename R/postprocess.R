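#' Plot an activation map with isochrones
#'
#' Filled-contour rendering of an activation-time map, with isochrone lines
#' labelled in ms. The map minimum is normalised to 0 before plotting.
#' Writes a PNG and never opens a window, so it is safe in headless batch
#' runs.
#'
#' @param actMap numeric matrix of activation times in ms (NA = missing).
#' @param outPath output PNG path.
#' @param isochroneStepMs spacing of isochrone lines in ms; NULL lets the
#'   plotting backend choose its default levels.
#' @param title plot title.
#' @return \code{outPath}, invisibly.
#' @export
plotActivationMap <- function(actMap, outPath, isochroneStepMs = NULL,
                              title = "Activation map") {
    stopifnot(is.matrix(actMap))
    ok <- !is.na(actMap)
    if (!any(ok))
        stop("activation map is entirely missing")
    if (nrow(actMap) < 3L || ncol(actMap) < 3L || sum(ok) < 9L)
        stop("activation map needs at least a 3x3 block of valid pixels")
    z <- actMap - min(actMap, na.rm = TRUE)
    zmax <- max(z, na.rm = TRUE)
    levels <- if (!is.null(isochroneStepMs)) {
        if (isochroneStepMs <= 0) stop("'isochroneStepMs' must be positive")
        seq(0, zmax + isochroneStepMs, by = isochroneStepMs)
    } else {
        pretty(c(0, zmax), n = 10)
    }
    if (length(levels) < 2L) levels <- c(0, max(zmax, 1))
    ## orient like the image: x = column, y = row (top row on top)
    zt <- t(z)[, rev(seq_len(nrow(z))), drop = FALSE]
    grDevices::png(outPath, width = 640, height = 560)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::filled.contour(
        x = seq_len(ncol(z)), y = seq_len(nrow(z)), z = zt,
        levels = levels,
        color.palette = grDevices::hcl.colors,
        main = title, xlab = "column", ylab = "row",
        plot.axes = {
            graphics::axis(1); graphics::axis(2)
            graphics::contour(seq_len(ncol(z)), seq_len(nrow(z)), zt,
                              levels = levels, add = TRUE, labcex = 0.9)
        },
        key.title = graphics::title(main = "ms", cex.main = 0.9))
    invisible(outPath)
}

#' Conduction velocity between pairs of points on an activation map
#'
#' Speed = pitch x Euclidean pixel distance / |activation-time
#' difference|. Pairs whose time difference is below \code{minDtMs} yield
#' NA with a warning (the wavefront is effectively simultaneous there).
#'
#' @param actMap numeric matrix of activation times in ms.
#' @param pointPairs numeric matrix with columns \code{r1, c1, r2, c2}
#'   (one row per pair, 1-based pixel indices).
#' @param pixelPitchMm physical pixel size in mm.
#' @param minDtMs smallest usable |time difference| (default 1e-6 ms).
#' @return Numeric vector of speeds in mm/ms, one per pair.
#' @examples
#' act <- outer(0:15, rep(1, 8)) * 2   # planar wave down the rows, 2 ms/px
#' cvBetweenPoints(act, cbind(1, 1, 11, 1), pixelPitchMm = 0.1)  # 0.05
#' @export
cvBetweenPoints <- function(actMap, pointPairs, pixelPitchMm,
                            minDtMs = 1e-6) {
    stopifnot(is.matrix(actMap))
    if (pixelPitchMm <= 0) stop("'pixelPitchMm' must be positive")
    pointPairs <- matrix(as.numeric(pointPairs), ncol = 4L)
    apply(pointPairs, 1L, function(p) {
        r1 <- p[1L]; c1 <- p[2L]; r2 <- p[3L]; c2 <- p[4L]
        if (any(c(r1, r2) < 1) || any(c(r1, r2) > nrow(actMap)) ||
            any(c(c1, c2) < 1) || any(c(c1, c2) > ncol(actMap)))
            stop("point outside the activation map")
        t1 <- actMap[r1, c1]; t2 <- actMap[r2, c2]
        if (is.na(t1) || is.na(t2))
            stop("point falls on a missing pixel of the activation map")
        dtms <- abs(t2 - t1)
        if (dtms < minDtMs) {
            warning("activation-time difference below tolerance; ",
                    "speed undefined for pair (", r1, ",", c1, ")-(",
                    r2, ",", c2, ")")
            return(NA_real_)
        }
        pixelPitchMm * sqrt((r2 - r1)^2 + (c2 - c1)^2) / dtms
    })
}

#' Local conduction velocity by polynomial surface fitting
#'
#' At every pixel, a second-order bivariate polynomial
#' \code{T(x,y) = ax^2 + by^2 + cxy + dx + ey + f} is least-squares fitted
#' to the activation times in the surrounding square window (x, y in mm).
#' The activation-time gradient at the window centre is \code{g = (d, e)}
#' and the conduction velocity is \code{v = g / (g . g)}, giving speed
#' \code{1/|g|}: the fit smooths pixel-level noise while the reciprocal
#' gradient converts time-per-distance into distance-per-time. Pixels whose
#' window holds fewer than 6 valid activation times (the number of
#' polynomial coefficients), whose fit is rank-deficient, or whose gradient
#' magnitude is below \code{minGradMsPerMm} are marked invalid.
#'
#' @param actMap numeric matrix of activation times in ms.
#' @param windowRadiusPx half-width of the square fitting window in pixels
#'   (default 3).
#' @param pixelPitchMm physical pixel size in mm.
#' @param minGradMsPerMm smallest usable gradient magnitude
#'   (default 1e-9 ms/mm).
#' @return A [VelocityField-class] in mm/ms.
#' @export
baylyLocalCv <- function(actMap, windowRadiusPx = 3L, pixelPitchMm,
                         minGradMsPerMm = 1e-9) {
    stopifnot(is.matrix(actMap))
    w <- as.integer(windowRadiusPx)
    if (is.na(w) || w < 1L) stop("'windowRadiusPx' must be a positive integer")
    if (pixelPitchMm <= 0) stop("'pixelPitchMm' must be positive")
    nr <- nrow(actMap); nc <- ncol(actMap)
    vx <- vy <- speed <- matrix(NA_real_, nr, nc)
    valid <- matrix(FALSE, nr, nc)
    for (r in seq_len(nr)) {
        for (c in seq_len(nc)) {
            if (is.na(actMap[r, c])) next
            rr <- max(1L, r - w):min(nr, r + w)
            cc <- max(1L, c - w):min(nc, c + w)
            win <- actMap[rr, cc, drop = FALSE]
            ok <- !is.na(win)
            if (sum(ok) < 6L) next
            ## x along columns, y along rows, centred on the pixel (mm)
            x <- (rep(cc, each = length(rr))[ok] - c) * pixelPitchMm
            y <- (rep(rr, times = length(cc))[ok] - r) * pixelPitchMm
            tt <- win[ok]
            X <- cbind(x^2, y^2, x * y, x, y, 1)
            fit <- tryCatch(stats::lm.fit(X, tt), error = function(e) NULL)
            if (is.null(fit) || fit$rank < 6L) next
            g <- fit$coefficients[4:5]          # dT/dx, dT/dy at the centre
            g2 <- sum(g^2)
            if (sqrt(g2) < minGradMsPerMm) next
            vx[r, c] <- g[1L] / g2
            vy[r, c] <- g[2L] / g2
            speed[r, c] <- 1 / sqrt(g2)
            valid[r, c] <- TRUE
        }
    }
    new("VelocityField", vx = vx, vy = vy, speed = speed, valid = valid)
}

#' Map beat-to-beat alternans of a feature
#'
#' The per-beat maps of even wave passes (bins 1, 3, 5, ... in R's 1-based
#' indexing, i.e. the first, third, ... passes) are averaged, likewise the
#' odd passes, and per pixel the alternans magnitude is computed from the
#' even mean e and odd mean o as:
#' \itemize{
#'   \item \code{largeToSmall}: \code{max(e,o) / min(e,o)} (>= 1);
#'   \item \code{smape}: \code{|e - o| / (e + o)} (symmetric mean absolute
#'     percentage error, in [0, 1));
#'   \item \code{oneMinusRatio}: \code{1 - min(e,o) / max(e,o)}
#'     (in [0, 1)).
#' }
#' All three are parity-symmetric, so which phase is labelled "even" does
#' not affect them. The formulas assume a positive feature (amplitude,
#' duration); pixels where \code{min(e,o) <= 0} are NA with a warning.
#' Pixels lacking at least one even and one odd record are NA.
#'
#' @param x a [FeatureMaps-class] (then give \code{feature}) or a 3-D
#'   per-beat array \code{[row, col, bin]}.
#' @param feature feature name when \code{x} is a FeatureMaps.
#' @param metric \code{"smape"}, \code{"largeToSmall"} or
#'   \code{"oneMinusRatio"}.
#' @return An [AlternansMap-class].
#' @export
alternansMap <- function(x, feature = "amplitude",
                         metric = c("smape", "largeToSmall",
                                    "oneMinusRatio")) {
    metric <- match.arg(metric)
    if (is(x, "FeatureMaps")) {
        a <- perBeatMaps(x, feature)
        src <- feature
    } else {
        a <- x
        src <- if (is.character(feature)) feature else "feature"
    }
    if (length(dim(a)) != 3L)
        stop("per-beat input must be a 3-D array [row, col, bin]")
    nBins <- dim(a)[3L]
    if (nBins < 2L)
        stop("alternans needs at least 2 bins (one even, one odd pass)")
    evenIdx <- seq(1L, nBins, by = 2L)
    oddIdx <- seq(2L, nBins, by = 2L)
    binMean <- function(sub) apply(sub, c(1L, 2L), function(v)
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    e <- binMean(a[, , evenIdx, drop = FALSE])
    o <- binMean(a[, , oddIdx, drop = FALSE])
    hi <- pmax(e, o); lo <- pmin(e, o)
    defined <- !is.na(hi) & !is.na(lo)
    bad <- defined & (lo <= 0)
    if (any(bad))
        warning(sum(bad), " pixel(s) have a non-positive even/odd mean; ",
                "alternans undefined there")
    use <- defined & !bad
    vals <- matrix(NA_real_, nrow(e), ncol(e))
    vals[use] <- switch(metric,
        largeToSmall = hi[use] / lo[use],
        smape = (hi[use] - lo[use]) / (hi[use] + lo[use]),
        oneMinusRatio = 1 - lo[use] / hi[use])
    new("AlternansMap", metric = metric, values = vals,
        mapEven = e, mapOdd = o, sourceFeature = src)
}
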