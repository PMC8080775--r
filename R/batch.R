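#' Read and validate a batch run configuration
#'
#' Configurations are plain YAML or JSON files (or an equivalent named
#' list). Recognised fields: \code{inputs} (paths or globs to TIFF stacks
#' or frame folders), \code{mode} ("multi"/"single"/"hybrid"),
#' \code{frameIntervalMs}, \code{periodMs} or \code{intervalsMs} (custom
#' comb; multi/hybrid need exactly one of the two), \code{polarity},
#' \code{binFactor}, \code{maskPath}, \code{pixelPitchMm},
#' \code{outputDir}, and the [traceParams()] fields
#' (\code{smoothingWindow}, \code{smoothingOrder}, \code{driftPolyDegree},
#' \code{recoveryLevel}, \code{baselineMode}, \code{objectSelection},
#' \code{refinementWidthMs}).
#'
#' @param config path to a YAML/JSON file, or a named list.
#' @return The validated configuration list, with defaults filled in.
#' @export
readRunConfig <- function(config) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config))
            stop("config file not found: ", config)
        config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
            yaml::read_yaml(config)
        else jsonlite::read_json(config, simplifyVector = TRUE)
    }
    if (!is.list(config)) stop("config must be a file path or a named list")
    known <- c("inputs", "mode", "frameIntervalMs", "periodMs",
               "intervalsMs", "polarity", "binFactor", "maskPath",
               "pixelPitchMm", "outputDir", "smoothingWindow",
               "smoothingOrder", "driftPolyDegree", "recoveryLevel",
               "baselineMode", "objectSelection", "refinementWidthMs",
               "writePerBeat")
    unknown <- setdiff(names(config), known)
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "),
             "; valid fields are: ", paste(known, collapse = ", "))
    defaults <- list(mode = "multi", polarity = "peaks", binFactor = 1L,
                     frameIntervalMs = 1, smoothingWindow = 11L,
                     smoothingOrder = 4L, driftPolyDegree = 4L,
                     recoveryLevel = 0.8, baselineMode = "first",
                     objectSelection = "first", refinementWidthMs = 10,
                     outputDir = "opticomb-out", writePerBeat = TRUE)
    for (f in names(defaults))
        if (is.null(config[[f]])) config[[f]] <- defaults[[f]]
    if (is.null(config$inputs) || !length(config$inputs))
        stop("config field 'inputs' is required")
    config$mode <- match.arg(config$mode, c("multi", "single", "hybrid"))
    config$polarity <- match.arg(config$polarity, c("peaks", "troughs"))
    num <- c("frameIntervalMs", "binFactor", "recoveryLevel",
             "refinementWidthMs")
    for (f in num)
        if (!is.numeric(config[[f]]) || config[[f]] < 0)
            stop("config field '", f, "' must be a non-negative number")
    if (config$frameIntervalMs <= 0)
        stop("config field 'frameIntervalMs' must be positive")
    if (config$mode %in% c("multi", "hybrid")) {
        hasP <- !is.null(config$periodMs)
        hasI <- !is.null(config$intervalsMs)
        if (hasP == hasI)
            stop("mode '", config$mode, "' needs exactly one of ",
                 "'periodMs' or 'intervalsMs'")
        if (hasP && config$periodMs <= 0)
            stop("'periodMs' must be positive")
        if (hasI && any(config$intervalsMs <= 0))
            stop("'intervalsMs' must all be positive")
        if (config$mode == "hybrid" && !hasP)
            stop("hybrid mode requires 'periodMs' (the basic cycle length)")
    }
    config
}

configTraceParams <- function(cfg) {
    traceParams(smoothingWindow = cfg$smoothingWindow,
                smoothingOrder = cfg$smoothingOrder,
                driftPolyDegree = cfg$driftPolyDegree,
                recoveryLevel = cfg$recoveryLevel,
                baselineMode = cfg$baselineMode,
                objectSelection = cfg$objectSelection,
                polarity = cfg$polarity,
                refinementWidthMs = cfg$refinementWidthMs)
}

## Expand input specs: existing paths pass through, others are globbed.
expandInputs <- function(inputs) {
    out <- unlist(lapply(inputs, function(p) {
        if (file.exists(p)) p else Sys.glob(p)
    }))
    unique(out)
}

#' Analyse one recording file or frame folder
#'
#' Reads the input (multi-slice TIFF or frame folder), applies binning and
#' mask per the configuration, runs the configured analysis mode and writes
#' outputs into \code{outDir}: one \code{<feature>_beat_mean.csv} per
#' feature, per-bin CSVs \code{<feature>_binNN.csv} (multi-wave, when
#' \code{writePerBeat}), a \code{summary.json} with the scalar means and
#' run metadata, and \code{config.json}, a machine-readable copy of the
#' resolved configuration for reproducibility.
#'
#' @param input path to a TIFF stack or frame folder.
#' @param config resolved configuration (see [readRunConfig()]).
#' @param outDir output directory (created if needed).
#' @return The summary list, invisibly.
#' @export
analyzeRecordingFile <- function(input, config, outDir) {
    cfg <- readRunConfig(config)
    rec <- if (dir.exists(input))
        readImageFolder(input, cfg$frameIntervalMs)
    else readTifStack(input, cfg$frameIntervalMs)
    if (cfg$binFactor > 1L) rec <- spatialBin(rec, cfg$binFactor)
    if (!is.null(cfg$maskPath)) rec <- applyMask(rec,
                                                 readMaskImage(cfg$maskPath))
    params <- configTraceParams(cfg)
    dt <- cfg$frameIntervalMs
    comb <- NULL; periodFrames <- NULL
    if (!is.null(cfg$intervalsMs))
        comb <- customComb(round(cfg$intervalsMs / dt))
    if (!is.null(cfg$periodMs))
        periodFrames <- as.integer(round(cfg$periodMs / dt))
    maps <- switch(cfg$mode,
        multi = analyzeMultiwave(rec, periodFrames = periodFrames,
                                 comb = comb, params = params),
        single = analyzeSinglewave(rec, params = params),
        hybrid = analyzeHybrid(rec, periodFrames, params = params))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (f in featureNames(maps)) {
        writeMapCsv(beatMeanMap(maps, f),
                    file.path(outDir, paste0(f, "_beat_mean.csv")))
        if (isTRUE(cfg$writePerBeat) && maps@mode == "multi") {
            a <- perBeatMaps(maps, f)
            for (b in seq_len(dim(a)[3L]))
                writeMapCsv(a[, , b],
                            file.path(outDir,
                                      sprintf("%s_bin%02d.csv", f, b)))
        }
    }
    nPix <- prod(dim(intensityData(rec))[1:2])
    amp <- beatMeanMap(maps, "amplitude")
    summary <- list(
        input = input,
        mode = maps@mode,
        nBins = dim(perBeatMaps(maps, "amplitude"))[3L],
        nPeaks = if (is.null(maps@clock)) NA else
            length(peakTimes(maps@clock)),
        pctMissingPixels = 100 * sum(is.na(amp)) / nPix,
        grandMean = as.list(maps@grandMean))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfgOut <- cfg
    cfgOut$inputs <- input
    jsonlite::write_json(cfgOut, file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message(sprintf("%s: %d bin(s), %.1f%% missing pixels", input,
                    summary$nBins, summary$pctMissingPixels))
    invisible(summary)
}

#' Run a batch of recordings with one configuration
#'
#' Every matched input is processed independently with identical
#' parameters; a failure on one recording is logged and the remaining
#' inputs are still processed. Results land in one sub-directory of
#' \code{outputDir} per recording, plus an \code{aggregate.json} collecting
#' the per-recording scalar summaries -- convenient for running a whole
#' experiment (or a drug screen) in one call.
#'
#' @param config path to a YAML/JSON configuration or a named list
#'   (see [readRunConfig()]).
#' @return Invisibly, a list with \code{status} (0 = all succeeded,
#'   1 = partial failure) and \code{summaries}.
#' @export
runBatch <- function(config) {
    cfg <- readRunConfig(config)
    inputs <- expandInputs(cfg$inputs)
    if (!length(inputs))
        stop("no inputs matched: ", paste(cfg$inputs, collapse = ", "))
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    summaries <- list()
    failed <- character(0)
    for (input in inputs) {
        name <- tools::file_path_sans_ext(basename(input))
        outDir <- file.path(cfg$outputDir, name)
        res <- tryCatch(analyzeRecordingFile(input, cfg, outDir),
                        error = function(e) {
                            message("FAILED ", input, ": ",
                                    conditionMessage(e))
                            NULL
                        })
        if (is.null(res)) failed <- c(failed, input)
        else summaries[[name]] <- res
    }
    agg <- list(nInputs = length(inputs), nFailed = length(failed),
                failed = failed, recordings = summaries)
    jsonlite::write_json(agg, file.path(cfg$outputDir, "aggregate.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(status = if (length(failed)) 1L else 0L,
                   summaries = summaries))
}
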