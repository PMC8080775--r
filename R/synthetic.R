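## Seed-scoped RNG: run fn under a seed, restoring the caller's RNG state.
withSeed <- function(seed, fn) {
    if (is.null(seed)) return(fn())
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    fn()
}

#' Build a single-transient template
#'
#' Two stylised transient shapes with closed-form features:
#' \code{"apTent"} is a piecewise-linear rise and fall (a tent), so every
#' duration, activation and recovery time has an exact analytic value;
#' \code{"catSkewed"} has a linear rise and an exponential decay (time
#' constant \code{fallFrames / 3}), mimicking the fast-rise/slow-decay
#' asymmetry of calcium transients. Both start at 0, peak at
#' \code{riseFrames} (value \code{amplitude}), and have
#' \code{riseFrames + fallFrames + 1} samples.
#'
#' @param kind \code{"apTent"} or \code{"catSkewed"}.
#' @param riseFrames,fallFrames rise and fall lengths in frames (>= 1).
#' @param amplitude peak height (0 gives a flat template).
#' @return Numeric vector template.
#' @examples
#' tpl <- makeTransientTemplate("apTent", 10, 10)
#' analyticTransientFeatures("apTent", 10, 10, 1, level = 0.8)$durationFrames
#' @export
makeTransientTemplate <- function(kind = c("apTent", "catSkewed"),
                                  riseFrames, fallFrames, amplitude = 1) {
    kind <- match.arg(kind)
    riseFrames <- as.integer(riseFrames)
    fallFrames <- as.integer(fallFrames)
    if (is.na(riseFrames) || riseFrames < 1L ||
        is.na(fallFrames) || fallFrames < 1L)
        stop("'riseFrames' and 'fallFrames' must be positive integers")
    t <- 0:(riseFrames + fallFrames)
    up <- t <= riseFrames
    v <- numeric(length(t))
    v[up] <- amplitude * t[up] / riseFrames
    v[!up] <- switch(kind,
        apTent = amplitude * (1 - (t[!up] - riseFrames) / fallFrames),
        catSkewed = amplitude * exp(-3 * (t[!up] - riseFrames) / fallFrames))
    v
}

#' Closed-form features of a transient template
#'
#' Analytic duration, activation time and recovery time of a template from
#' [makeTransientTemplate()] at a given recovery level, measured from the
#' transient's own start with baseline 0. These are the ground-truth values
#' the extraction pipeline is scored against.
#'
#' @inheritParams makeTransientTemplate
#' @param level recovery level in (0,1) (0.8 = APD80).
#' @return List with \code{durationFrames}, \code{activationFrames} (first
#'   half-max crossing), \code{recoveryFrames} (crossing of the recovery
#'   level on the downstroke), \code{peakFrames}.
#' @export
analyticTransientFeatures <- function(kind = c("apTent", "catSkewed"),
                                      riseFrames, fallFrames,
                                      amplitude = 1, level = 0.8) {
    kind <- match.arg(kind)
    if (!(level > 0 && level < 1)) stop("'level' must be in (0,1)")
    up <- (1 - level) * riseFrames          # rise crossing of (1-level)*amp
    act <- 0.5 * riseFrames                 # rise crossing of half-max
    down <- switch(kind,
        apTent = riseFrames + level * fallFrames,
        catSkewed = riseFrames - fallFrames / 3 * log(1 - level))
    list(durationFrames = down - up, activationFrames = act,
         recoveryFrames = down, peakFrames = riseFrames)
}

#' Generate a transient train with exact ground truth
#'
#' Copies of a template are pasted at stimulus times given by cumulative
#' inter-beat intervals; beat k (k = 0, 1, ...) is scaled by
#' \code{1 + alternansA * (-1)^k}, so even beats are the large ones and the
#' even/odd peak ratio is \code{(1+a)/(1-a)}. Optional slow polynomial
#' drift (in normalised time over [0,1]) and i.i.d. Gaussian noise are
#' added last. Transients must not overlap; back-to-back placement (next
#' stimulus exactly at the previous template's last sample + 1) is allowed
#' and produces a gap-free trace whose unique per-beat minima sit exactly
#' at the stimulus frames.
#'
#' @param template numeric template from [makeTransientTemplate()].
#' @param intervalsFrames inter-stimulus intervals in frames (the train has
#'   \code{length(intervalsFrames) + 1} beats).
#' @param nFrames trace length in frames.
#' @param noiseSd standard deviation of additive Gaussian noise.
#' @param driftCoefs polynomial drift coefficients (constant first),
#'   evaluated over normalised time; NULL = no drift.
#' @param alternansA amplitude-alternans factor in [0, 1).
#' @param seed RNG seed for the noise (restores the caller's RNG state).
#' @param startFrame frame of the first stimulus (1-based, default 1).
#' @return A list with \code{trace} and \code{truth} (stimulusFrames,
#'   peakFrames, scales, noiseSd, driftCoefs, alternansA, template info).
#' @export
makeTrace <- function(template, intervalsFrames, nFrames, noiseSd = 0,
                      driftCoefs = NULL, alternansA = 0, seed = NULL,
                      startFrame = 1L) {
    intervalsFrames <- as.integer(intervalsFrames)
    nFrames <- as.integer(nFrames)
    if (!(alternansA >= 0 && alternansA < 1))
        stop("'alternansA' must be in [0, 1)")
    stim <- as.integer(startFrame) + c(0L, cumsum(intervalsFrames))
    len <- length(template)
    if (any(diff(stim) < len))
        stop("transients overlap: an interval is shorter than the template")
    if (stim[length(stim)] + len - 1L > nFrames)
        stop("'nFrames' too small for the last transient")
    k <- seq_along(stim) - 1L
    scales <- 1 + alternansA * (-1)^k
    trace <- numeric(nFrames)
    for (i in seq_along(stim))
        trace[stim[i]:(stim[i] + len - 1L)] <- template * scales[i]
    if (!is.null(driftCoefs)) {
        u <- (seq_len(nFrames) - 1) / (nFrames - 1)
        drift <- rowSums(outer(u, seq_along(driftCoefs) - 1, `^`) *
                             rep(driftCoefs, each = nFrames))
        trace <- trace + drift
    }
    if (noiseSd > 0)
        trace <- trace + withSeed(seed, function() stats::rnorm(nFrames,
                                                                0, noiseSd))
    peakOffset <- which.max(template) - 1L
    list(trace = trace,
         truth = list(stimulusFrames = stim,
                      peakFrames = stim + peakOffset,
                      scales = scales, alternansA = alternansA,
                      noiseSd = noiseSd, driftCoefs = driftCoefs,
                      templateLength = len, peakOffsetFrames = peakOffset))
}

#' Generate a planar-wave recording with known conduction velocity
#'
#' A wave propagates down the rows: the activation of row r is delayed by
#' \code{round((r - 1) / speedPxPerFrame)} frames (speed \code{Inf} gives a
#' spatially uniform flash train). Every pixel receives the same transient
#' train, shifted by its row delay. The wave must fully traverse the grid
#' within one basic cycle length.
#'
#' @param rows,cols grid size.
#' @param speedPxPerFrame propagation speed in pixels per frame
#'   (\code{Inf} = simultaneous).
#' @param bclFrames basic cycle length in frames.
#' @param nBeats number of wave passes.
#' @param template transient template (default: gap-free calcium-style
#'   transient filling one BCL).
#' @param noiseSd additive Gaussian noise SD.
#' @param seed RNG seed for the noise.
#' @param alternansA amplitude-alternans factor in [0, 1).
#' @param frameIntervalMs milliseconds per frame.
#' @param mask optional logical mask carried by the recording.
#' @return List with \code{recording} ([OMRecording-class]) and
#'   \code{truth} (row delays, per-beat stimulus frames of row 1, template
#'   info, speed).
#' @export
makePlanarWaveStack <- function(rows, cols, speedPxPerFrame, bclFrames,
                                nBeats, template = NULL, noiseSd = 0,
                                seed = NULL, alternansA = 0,
                                frameIntervalMs = 1, mask = NULL) {
    rows <- as.integer(rows); cols <- as.integer(cols)
    bclFrames <- as.integer(bclFrames); nBeats <- as.integer(nBeats)
    if (nBeats < 2L) stop("'nBeats' must be at least 2")
    if (is.null(template))
        template <- makeTransientTemplate("catSkewed",
                                          riseFrames = max(2L,
                                              bclFrames %/% 10L),
                                          fallFrames = bclFrames - 1L -
                                              max(2L, bclFrames %/% 10L))
    delays <- if (is.infinite(speedPxPerFrame)) rep(0L, rows) else
        as.integer(round((seq_len(rows) - 1L) / speedPxPerFrame))
    maxDelay <- max(delays)
    if (maxDelay >= bclFrames)
        stop("wave does not traverse the grid within one cycle; increase ",
             "'speedPxPerFrame' or 'bclFrames'")
    nFrames <- maxDelay + nBeats * bclFrames
    intervals <- rep(bclFrames, nBeats - 1L)
    rowTraces <- lapply(seq_len(rows), function(r)
        makeTrace(template, intervals, nFrames, noiseSd = 0,
                  alternansA = alternansA,
                  startFrame = 1L + delays[r]))
    arr <- array(0, dim = c(rows, cols, nFrames))
    for (r in seq_len(rows))
        arr[r, , ] <- matrix(rowTraces[[r]]$trace, nrow = cols,
                             ncol = nFrames, byrow = TRUE)
    if (noiseSd > 0)
        arr <- arr + withSeed(seed, function()
            array(stats::rnorm(length(arr), 0, noiseSd), dim = dim(arr)))
    rec <- OMRecording(arr, frameIntervalMs, mask = mask)
    list(recording = rec,
         truth = list(delaysFrames = delays,
                      speedPxPerFrame = speedPxPerFrame,
                      bclFrames = bclFrames, nBeats = nBeats,
                      stimulusFramesRow1 =
                          rowTraces[[1L]]$truth$stimulusFrames,
                      peakFramesRow1 = rowTraces[[1L]]$truth$peakFrames,
                      peakOffsetFrames =
                          rowTraces[[1L]]$truth$peakOffsetFrames,
                      template = template, noiseSd = noiseSd,
                      alternansA = alternansA))
}

#' Generate a discordant-alternans recording
#'
#' Spatially uniform flash train whose amplitude alternation flips phase
#' across a nodal row: above the nodal row even beats are the large ones,
#' below it the odd beats are, and the alternation magnitude tapers
#' linearly to 0 on the nodal row itself (over \code{taperRows} rows on
#' each side). This reproduces the hallmark pattern of discordant
#' alternans: zones oscillating in opposite phase separated by a
#' non-alternating nodal line.
#'
#' @inheritParams makePlanarWaveStack
#' @param a alternation factor in [0, 1) far from the nodal row.
#' @param nodalRow row index of the nodal line.
#' @param taperRows rows over which the alternation ramps from 0 to a
#'   (default 1: only the nodal row is alternation-free).
#' @return List with \code{recording} and \code{truth} (per-row alternans
#'   factor with sign = phase, template info).
#' @export
makeDiscordantAlternansStack <- function(rows, cols, a, nodalRow,
                                         bclFrames, nBeats,
                                         template = NULL, taperRows = 1L,
                                         noiseSd = 0, seed = NULL,
                                         frameIntervalMs = 1) {
    rows <- as.integer(rows); cols <- as.integer(cols)
    if (!(a >= 0 && a < 1)) stop("'a' must be in [0, 1)")
    if (is.null(template))
        template <- makeTransientTemplate("catSkewed",
                                          riseFrames = max(2L,
                                              bclFrames %/% 10L),
                                          fallFrames = bclFrames - 1L -
                                              max(2L, bclFrames %/% 10L))
    ## signed per-row factor: + above the nodal row, - below, 0 on it
    dist <- seq_len(rows) - nodalRow
    aRow <- a * pmax(-1, pmin(1, -dist / taperRows))
    nFrames <- nBeats * as.integer(bclFrames)
    intervals <- rep(as.integer(bclFrames), nBeats - 1L)
    stim <- c(1L, 1L + cumsum(intervals))
    k <- seq_along(stim) - 1L
    arr <- array(0, dim = c(rows, cols, nFrames))
    for (r in seq_len(rows)) {
        scales <- 1 + aRow[r] * (-1)^k  # signed factor flips the phase
        tr <- numeric(nFrames)
        for (i in seq_along(stim))
            tr[stim[i]:(stim[i] + length(template) - 1L)] <-
                template * scales[i]
        arr[r, , ] <- matrix(tr, nrow = cols, ncol = nFrames, byrow = TRUE)
    }
    if (noiseSd > 0)
        arr <- arr + withSeed(seed, function()
            array(stats::rnorm(length(arr), 0, noiseSd), dim = dim(arr)))
    list(recording = OMRecording(arr, frameIntervalMs),
         truth = list(aRowSigned = aRow, nodalRow = nodalRow, a = a,
                      bclFrames = bclFrames, nBeats = nBeats,
                      template = template, noiseSd = noiseSd))
}

#' Write a fixture stack and its ground truth to disk
#'
#' Convenience for end-to-end tests and the command-line \code{make-fixture}
#' subcommand: the recording goes to a 16-bit TIFF stack (scaled so the
#' intensity range uses the integer range well) and the ground truth to a
#' JSON sidecar.
#'
#' @param fixture list with \code{recording} and \code{truth} from one of
#'   the generators.
#' @param path output TIFF path; the JSON sidecar gets extension
#'   \code{.truth.json}.
#' @param scale integer scale applied before 16-bit quantisation
#'   (default 1000).
#' @return \code{path}, invisibly.
#' @export
writeFixtureStack <- function(fixture, path, scale = 1000) {
    rec <- fixture$recording
    writeTifStack(rec, path, scale = scale)
    truth <- fixture$truth
    truth$template <- NULL  # arrays don't belong in the sidecar
    truth$quantisationScale <- scale
    truth$frameIntervalMs <- frameInterval(rec)
    jsonlite::write_json(truth, sub("\\.tiff?$", ".truth.json", path,
                                    ignore.case = TRUE),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}
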