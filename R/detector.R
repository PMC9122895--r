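#' @include AllClasses.R boxes.R
NULL

#' Filter count of the convolutional layer ahead of a YOLO head
#'
#' A one-stage detector head predicts, for each of its 3 anchor shapes, a
#' box (4 values), an objectness score and one score per class, so the
#' layer needs (classes + 5) x 3 filters: 18 for a one-class worm detector
#' and 27 for the four-class overlap detector.
#'
#' @param nClasses number of classes (>= 1).
#' @return integer filter count.
#' @examples
#' headFilterCount(1)  # 18
#' headFilterCount(4)  # 27
#' @export
headFilterCount <- function(nClasses) {
    nClasses <- .assertCount(nClasses, "nClasses", 1L)
    (nClasses + 5L) * 3L
}

#' Detector post-processing configuration
#'
#' @param nClasses number of classes (1 for OCC, 4 for MCC).
#' @param confidenceThreshold minimum confidence kept (default 0.30).
#' @param nmsIouThreshold IoU above which a lower-confidence same-class box
#'   is suppressed (default 0.45).
#' @return a validated list of class \code{detectorConfig}.
#' @export
detectorConfig <- function(nClasses = 1L, confidenceThreshold = 0.30,
                           nmsIouThreshold = 0.45) {
    cfg <- list(nClasses = .assertCount(nClasses, "nClasses", 1L),
                confidenceThreshold = .assertScalarNum(confidenceThreshold,
                    "confidenceThreshold", 0, 1),
                nmsIouThreshold = .assertScalarNum(nmsIouThreshold,
                    "nmsIouThreshold", 0, 1))
    class(cfg) <- "detectorConfig"
    cfg
}

#' Confidence filtering
#'
#' Keeps detections with confidence >= threshold (the boundary is kept),
#' preserving order.
#'
#' @param dets detection data.frame (x, y, w, h, class, confidence).
#' @param threshold confidence cutoff in [0, 1].
#' @return filtered detection data.frame.
#' @export
confidenceFilter <- function(dets, threshold = 0.30) {
    .assertBoxes(dets, "dets", needConfidence = TRUE)
    .assertScalarNum(threshold, "threshold", 0, 1)
    dets[dets$confidence >= threshold, , drop = FALSE]
}

#' Greedy per-class non-maximum suppression
#'
#' Classic greedy NMS run independently for each class label: within a
#' class, boxes are visited in decreasing confidence (ties broken by
#' smaller x, then smaller y, then input order); a visited box is kept
#' unless its IoU with an already-kept box of the same class strictly
#' exceeds \code{iouThreshold}. Heavily overlapped same-class boxes
#' therefore collapse to one — the mechanism that makes a one-class
#' detector undercount overlapped worms — while boxes of different classes
#' never suppress each other.
#'
#' @param dets detection data.frame (x, y, w, h, class, confidence).
#' @param iouThreshold suppression threshold in [0, 1]; at 1.0 only exact
#'   duplicates are suppressed.
#' @return the kept subset of \code{dets} (original row order).
#' @export
nms <- function(dets, iouThreshold = 0.45) {
    .assertBoxes(dets, "dets", needConfidence = TRUE)
    .assertScalarNum(iouThreshold, "iouThreshold", 0, 1)
    if (nrow(dets) <= 1L) return(dets)
    keep <- logical(nrow(dets))
    for (cl in unique(dets$class)) {
        rows <- which(dets$class == cl)
        d <- dets[rows, , drop = FALSE]
        ord <- order(-d$confidence, d$x, d$y, seq_len(nrow(d)))
        M <- iouMatrix(d, d)
        kept <- integer(0)
        for (i in ord) {
            ## suppress on IoU strictly above the threshold; exact
            ## duplicates (IoU 1) are always suppressed, so at threshold
            ## 1.0 only duplicates go
            if (length(kept) == 0L ||
                all(M[kept, i] <= iouThreshold & M[kept, i] < 1 - 1e-12))
                kept <- c(kept, i)
        }
        keep[rows[kept]] <- TRUE
    }
    dets[keep, , drop = FALSE]
}

#' Complete-IoU (CIoU) regression loss between two boxes
#'
#' 1 - IoU + rho^2 / c^2 + alpha v, where rho is the centre distance, c the
#' diagonal of the smallest box enclosing both, v = (4/pi^2) (arctan(w_g/h_g)
#' - arctan(w/h))^2 the aspect-ratio term and alpha = v / ((1 - IoU) + v).
#' Zero iff the boxes coincide.
#'
#' @param pred,gt boxes: \code{c(x, y, w, h)} vectors or one-row data.frames.
#' @return nonnegative loss value.
#' @export
ciouLoss <- function(pred, gt) {
    p <- .asBoxVec(pred); g <- .asBoxVec(gt)
    iou <- boxIoU(p, g)
    pc <- c(p[1] + p[3] / 2, p[2] + p[4] / 2)
    gc <- c(g[1] + g[3] / 2, g[2] + g[4] / 2)
    rho2 <- sum((pc - gc)^2)
    cw <- max(p[1] + p[3], g[1] + g[3]) - min(p[1], g[1])
    ch <- max(p[2] + p[4], g[2] + g[4]) - min(p[2], g[2])
    c2 <- cw^2 + ch^2
    v <- (4 / pi^2) * (atan(g[3] / g[4]) - atan(p[3] / p[4]))^2
    alpha <- if (v == 0) 0 else v / ((1 - iou) + v)
    (1 - iou) + rho2 / c2 + alpha * v
}

#' Error model of the simulated detector
#'
#' @param jitterSd standard deviation (pixels) of the position jitter added
#'   to each candidate box; box sizes are jittered at half this value.
#' @param kCandidates candidate anchor boxes emitted per true object
#'   (>= 1); the surplus is what NMS must remove.
#' @param missRate probability that an object emits no candidates.
#' @param falseRate expected false proposals per true object (Poisson).
#' @param trueConfShape Beta(shape1, shape2) parameters of true-candidate
#'   confidences (length 2; mean 0.8 by default, nearly always above the
#'   0.30 cutoff).
#' @param falseConfRange uniform confidence range of false proposals.
#' @param falseSizeRange side-length range (pixels) of false-proposal boxes.
#' @return a validated list of class \code{detectorErrorModel}.
#' @export
detectorErrorModel <- function(jitterSd = 2, kCandidates = 2L,
                               missRate = 0.02, falseRate = 0.02,
                               trueConfShape = c(8, 2),
                               falseConfRange = c(0.05, 0.6),
                               falseSizeRange = c(20, 60)) {
    em <- list(jitterSd = .assertScalarNum(jitterSd, "jitterSd", 0),
               kCandidates = .assertCount(kCandidates, "kCandidates", 1L),
               missRate = .assertScalarNum(missRate, "missRate", 0, 1),
               falseRate = .assertScalarNum(falseRate, "falseRate", 0),
               trueConfShape = as.numeric(trueConfShape),
               falseConfRange = as.numeric(falseConfRange),
               falseSizeRange = as.numeric(falseSizeRange))
    class(em) <- "detectorErrorModel"
    em
}

## jitter one gt box into k candidate boxes, clipped to the frame
.jitterBoxes <- function(box, k, sd, W, H) {
    w <- pmax(4, box$w + rnorm(k, 0, sd / 2))
    h <- pmax(4, box$h + rnorm(k, 0, sd / 2))
    x <- box$x + rnorm(k, 0, sd)
    y <- box$y + rnorm(k, 0, sd)
    x <- pmin(pmax(x, 0), W - w)
    y <- pmin(pmax(y, 0), H - h)
    data.frame(x = x, y = y, w = w, h = h)
}

#' Simulate a trained detector on a scene
#'
#' Desk-scale stand-in for a trained one-stage network, built so that the
#' post-processing chain — confidence filtering then per-class NMS — acts on
#' realistic candidate sets. In \code{"occ"} mode each worm (unit box) emits
#' jittered class-1 candidates, so candidates of heavily overlapped worms
#' exceed the NMS IoU threshold and collapse to a single detection: the
#' one-class undercounting mechanism. In \code{"mcc"} mode candidates are
#' emitted per worm group with the group's class label, so each overlap
#' group survives as one class-n detection. Both modes add false proposals
#' and drop missed objects per the error model.
#'
#' @param scene a \linkS4class{WormScene}.
#' @param mode \code{"occ"} or \code{"mcc"}.
#' @param errorModel a \code{\link{detectorErrorModel}}; with zero jitter,
#'   miss and false rates the detector is perfect up to NMS.
#' @param config a \code{\link{detectorConfig}}; when NULL, defaults to one
#'   class in \code{"occ"} mode and four in \code{"mcc"} mode.
#' @param seed optional seed (caller RNG state restored).
#' @return detection data.frame (x, y, w, h, class, confidence).
#' @export
simulateDetector <- function(scene, mode = c("occ", "mcc"),
                             errorModel = detectorErrorModel(),
                             config = NULL,
                             seed = NULL) {
    stopifnot(is(scene, "WormScene"))
    mode <- match.arg(mode)
    if (is.null(config))
        config <- detectorConfig(nClasses = if (mode == "occ") 1L else 4L)
    stopifnot(inherits(errorModel, "detectorErrorModel"),
              inherits(config, "detectorConfig"))
    gt <- if (mode == "occ") scene@unitBoxes else scene@groupBoxes
    W <- nrow(scene@image); H <- ncol(scene@image)
    .withSeed(seed, {
        cands <- list()
        for (i in seq_len(nrow(gt))) {
            if (errorModel$missRate > 0 &&
                runif(1) < errorModel$missRate) next
            b <- .jitterBoxes(gt[i, ], errorModel$kCandidates,
                              errorModel$jitterSd, W, H)
            b$class <- if (mode == "occ") 1L else as.integer(gt$class[i])
            b$confidence <- rbeta(nrow(b), errorModel$trueConfShape[1],
                                  errorModel$trueConfShape[2])
            cands[[length(cands) + 1L]] <- b
        }
        nFalse <- if (errorModel$falseRate > 0)
            rpois(1, errorModel$falseRate * max(1, nrow(gt))) else 0L
        if (nFalse > 0) {
            fw <- runif(nFalse, errorModel$falseSizeRange[1],
                        errorModel$falseSizeRange[2])
            fh <- runif(nFalse, errorModel$falseSizeRange[1],
                        errorModel$falseSizeRange[2])
            f <- data.frame(
                x = runif(nFalse, 0, W - fw), y = runif(nFalse, 0, H - fh),
                w = fw, h = fh,
                class = sample.int(config$nClasses, nFalse, replace = TRUE),
                confidence = runif(nFalse, errorModel$falseConfRange[1],
                                   errorModel$falseConfRange[2]))
            cands[[length(cands) + 1L]] <- f
        }
        dets <- if (length(cands)) do.call(rbind, cands)
                else data.frame(x = numeric(0), y = numeric(0),
                                w = numeric(0), h = numeric(0),
                                class = integer(0), confidence = numeric(0))
        rownames(dets) <- NULL
        dets <- confidenceFilter(dets, config$confidenceThreshold)
        nms(dets, config$nmsIouThreshold)
    })
}
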