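#' @include wormgen.R detector.R evaluation.R
NULL

#' Configuration of the OCC-vs-MCC comparison experiment
#'
#' A single global seed fans out to fixed per-stage offsets (shape library,
#' per-scene generation, per-scene detector runs), so one knob reproduces
#' the whole experiment. Unknown names in \code{...} or in a YAML override
#' are rejected.
#'
#' @param seed global seed.
#' @param nScenes number of simulated fields.
#' @param libSize shape-library size.
#' @param nModelsRange worm groups per field (uniform range).
#' @param classMix group-class sampling probabilities (sum to 1); the
#'   default leans on classes 3-4, the overlap-rich regime where one-class
#'   counting fails.
#' @param fieldSize c(width, height) pixels.
#' @param iouThreshold evaluation matching threshold.
#' @param confidenceThreshold,nmsIouThreshold detector post-processing
#'   thresholds.
#' @param jitterSd,kCandidates,missRate,falseRate error-model knobs (see
#'   \code{\link{detectorErrorModel}}).
#' @param outDir optional directory for report files.
#' @return validated list of class \code{experimentConfig}.
#' @export
experimentConfig <- function(seed = 1, nScenes = 20, libSize = 30,
                             nModelsRange = c(14, 20),
                             classMix = c(0.05, 0.15, 0.40, 0.40),
                             fieldSize = c(704, 528), iouThreshold = 0.5,
                             confidenceThreshold = 0.30,
                             nmsIouThreshold = 0.45, jitterSd = 2,
                             kCandidates = 2, missRate = 0.02,
                             falseRate = 0.02, outDir = NULL) {
    cfg <- list(seed = .assertCount(seed, "seed", 0L),
                nScenes = .assertCount(nScenes, "nScenes", 1L),
                libSize = .assertCount(libSize, "libSize", 1L),
                nModelsRange = as.numeric(nModelsRange),
                classMix = as.numeric(classMix),
                fieldSize = as.numeric(fieldSize),
                iouThreshold = .assertScalarNum(iouThreshold,
                                                "iouThreshold", 0, 1),
                confidenceThreshold = .assertScalarNum(confidenceThreshold,
                    "confidenceThreshold", 0, 1),
                nmsIouThreshold = .assertScalarNum(nmsIouThreshold,
                    "nmsIouThreshold", 0, 1),
                jitterSd = .assertScalarNum(jitterSd, "jitterSd", 0),
                kCandidates = .assertCount(kCandidates, "kCandidates", 1L),
                missRate = .assertScalarNum(missRate, "missRate", 0, 1),
                falseRate = .assertScalarNum(falseRate, "falseRate", 0),
                outDir = outDir)
    class(cfg) <- "experimentConfig"
    cfg
}

#' Read an experiment configuration from YAML
#'
#' YAML keys override \code{\link{experimentConfig}} defaults; unknown keys
#' raise an error naming the key.
#'
#' @param path YAML file path.
#' @return an \code{experimentConfig}.
#' @export
readExperimentConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(experimentConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    do.call(experimentConfig, vals)
}

## evaluate one detector mode over a scene set
.evaluateMode <- function(scenes, detsList, mode, iouThreshold) {
    tp <- 0; fp <- 0; fn <- 0
    errors <- integer(length(scenes))
    perImage <- vector("list", length(scenes))
    for (s in seq_along(scenes)) {
        cc <- matchAndCount(detsList[[s]], scenes[[s]], mode, iouThreshold)
        tp <- tp + cc$tp; fp <- fp + cc$fp; fn <- fn + cc$fn
        nGt <- nWorms(scenes[[s]])
        nDet <- if (mode == "occ") nrow(detsList[[s]])
                else sum(detsList[[s]]$class)
        errors[s] <- detectionError(nDet, nGt)
        perImage[[s]] <- data.frame(image = s, mode = mode, nGt = nGt,
                                    nDet = nDet, tp = cc$tp, fp = cc$fp,
                                    fn = cc$fn, error = errors[s])
    }
    counts <- evalCounts(tp, fp, fn)
    p <- detectionPrecision(counts)
    r <- detectionRecall(counts)
    curve <- prCurve(detsList, scenes, mode, iouThreshold)
    list(counts = counts, precision = p, recall = r, f1 = f1Score(p, r),
         ap = averagePrecision(curve), curve = curve,
         errors = summarizeErrors(errors),
         perImage = do.call(rbind, perImage),
         nBoxes = sum(vapply(detsList, nrow, integer(1))),
         nBoxesDivided = sum(vapply(detsList, function(d)
             sum(d$class), numeric(1))))
}

#' Run the one-class vs multi-class comparison experiment
#'
#' Generates a seeded scene set, runs the simulated detector in both the
#' one-class and the multi-class mode on every scene, evaluates both with
#' the division-based counting scheme, and returns (optionally writes) a
#' side-by-side report: precision, recall, F1, AP, detection-error mean and
#' standard deviation, box totals and the full PR curves. Fully
#' reproducible from \code{config$seed}.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @return report list of class \code{experimentReport} with elements
#'   \code{config}, \code{scenes} (worm/group totals), \code{occ} and
#'   \code{mcc} (per-mode metrics), \code{perImage} (data.frame). When
#'   \code{config$outDir} is set, also writes \code{report.json},
#'   \code{per_image.csv}, \code{pr_occ.csv} and \code{pr_mcc.csv}.
#' @export
runExperiment <- function(config = experimentConfig()) {
    stopifnot(inherits(config, "experimentConfig"))
    library <- makeShapeLibrary(config$libSize, seed = config$seed + 1000L)
    scenes <- lapply(seq_len(config$nScenes), function(i)
        makeScene(library, nModelsRange = config$nModelsRange,
                  classMix = config$classMix, fieldSize = config$fieldSize,
                  seed = config$seed + 2000L + i))
    em <- detectorErrorModel(jitterSd = config$jitterSd,
                             kCandidates = config$kCandidates,
                             missRate = config$missRate,
                             falseRate = config$falseRate)
    runMode <- function(mode, offset) {
        cfg <- detectorConfig(nClasses = if (mode == "occ") 1L else 4L,
                              confidenceThreshold =
                                  config$confidenceThreshold,
                              nmsIouThreshold = config$nmsIouThreshold)
        dets <- lapply(seq_along(scenes), function(i)
            simulateDetector(scenes[[i]], mode, em, cfg,
                             seed = config$seed + offset + i))
        .evaluateMode(scenes, dets, mode, config$iouThreshold)
    }
    occ <- runMode("occ", 3000L)
    mcc <- runMode("mcc", 4000L)
    report <- list(config = config,
                   scenes = list(n = length(scenes),
                                 worms = sum(vapply(scenes, nWorms,
                                                    integer(1))),
                                 groups = sum(vapply(scenes, function(s)
                                     nrow(groupBoxes(s)), integer(1)))),
                   occ = occ, mcc = mcc,
                   perImage = rbind(occ$perImage, mcc$perImage))
    class(report) <- "experimentReport"
    if (!is.null(config$outDir)) writeExperimentReport(report,
                                                       config$outDir)
    report
}

#' @export
print.experimentReport <- function(x, ...) {
    cat(sprintf("OCC vs MCC over %d scenes (%d worms in %d groups)\n",
                x$scenes$n, x$scenes$worms, x$scenes$groups))
    fmt <- function(m) sprintf(
        "precision %.3f  recall %.3f  F1 %.3f  AP %.3f  error %+.2f +/- %.2f",
        m$precision, m$recall, m$f1, m$ap, m$errors$mean, m$errors$sd)
    cat("  OCC:", fmt(x$occ), "\n")
    cat("  MCC:", fmt(x$mcc), "\n")
    invisible(x)
}

#' Write an experiment report to disk
#'
#' @param report an \code{experimentReport}.
#' @param outDir output directory (created if needed).
#' @return \code{outDir}, invisibly.
#' @export
writeExperimentReport <- function(report, outDir) {
    stopifnot(inherits(report, "experimentReport"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    modeJSON <- function(m) list(
        precision = m$precision, recall = m$recall, f1 = m$f1, ap = m$ap,
        errorMean = m$errors$mean, errorSd = m$errors$sd,
        tp = m$counts$tp, fp = m$counts$fp, fn = m$counts$fn,
        nBoxes = m$nBoxes, nBoxesDivided = m$nBoxesDivided)
    cfg <- unclass(report$config)
    cfg$outDir <- NULL
    jsonlite::write_json(
        list(config = cfg, scenes = report$scenes,
             occ = modeJSON(report$occ), mcc = modeJSON(report$mcc)),
        file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    write.csv(report$perImage, file.path(outDir, "per_image.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(report$occ$curve),
              file.path(outDir, "pr_occ.csv"), row.names = FALSE)
    write.csv(as.data.frame(report$mcc$curve),
              file.path(outDir, "pr_mcc.csv"), row.names = FALSE)
    invisible(outDir)
}
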