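#' @include AllClasses.R boxes.R detector.R
NULL

## Overlap-aware scoring. The central idea: a class-n detection claims n
## worms, so before counting it is DIVIDED into n unit (class-1) detections.
## Multi-class and one-class detectors then report on the same scale and the
## undercounting of a one-class detector becomes visible in recall and in
## the per-image detection error.

#' Divide multi-class detections into unit detections
#'
#' Each class-n detection is replaced by n class-1 detections sharing its
#' box and confidence; class-1 detections pass through. Worm count is
#' conserved: the output has \code{sum(dets$class)} rows.
#'
#' @param dets detection data.frame (x, y, w, h, class, confidence
#'   optional).
#' @return unit detection data.frame, all class 1.
#' @examples
#' divideClasses(wormBoxes(0, 0, 10, 10, class = 3))  # three unit rows
#' @export
divideClasses <- function(dets) {
    .assertBoxes(dets, "dets")
    if (nrow(dets) == 0L) return(dets)
    out <- dets[rep(seq_len(nrow(dets)), dets$class), , drop = FALSE]
    out$class <- 1L
    rownames(out) <- NULL
    out
}

#' Tally of detection outcomes
#'
#' @param tp,fp,fn nonnegative counts of true positives, false positives
#'   and false negatives. For a complete evaluation, tp + fn equals the
#'   ground-truth worm total.
#' @return list of class \code{EvalCounts}.
#' @export
evalCounts <- function(tp = 0, fp = 0, fn = 0) {
    for (v in c(tp, fp, fn))
        if (!is.numeric(v) || length(v) != 1L || v < 0 || !is.finite(v))
            stop("tp, fp and fn must be nonnegative counts", call. = FALSE)
    structure(list(tp = tp, fp = fp, fn = fn), class = "EvalCounts")
}

#' @export
print.EvalCounts <- function(x, ...) {
    cat(sprintf("EvalCounts: TP %g, FP %g, FN %g\n", x$tp, x$fp, x$fn))
    invisible(x)
}

.asGroundTruth <- function(gt) {
    if (is(gt, "WormScene"))
        gt <- list(unit = gt@unitBoxes, group = gt@groupBoxes)
    if (!is.list(gt) || !all(c("unit", "group") %in% names(gt)))
        stop("'gt' must be a WormScene or list(unit = , group = )",
             call. = FALSE)
    if (!is.null(gt$unit) && !is.null(gt$group) &&
        sum(gt$group$class) != nrow(gt$unit))
        stop("inconsistent ground truth: sum of group classes != worm count",
             call. = FALSE)
    gt
}

## greedy confidence-descending one-to-one matching; returns, per detection
## (in input order), the matched gt row index or NA
.greedyMatch <- function(dets, gtBoxes, iouThreshold) {
    match <- rep(NA_integer_, nrow(dets))
    if (nrow(dets) == 0L || nrow(gtBoxes) == 0L) return(match)
    conf <- if (is.null(dets$confidence)) rep(1, nrow(dets))
            else dets$confidence
    ord <- order(-conf, seq_len(nrow(dets)))
    M <- iouMatrix(dets, gtBoxes)
    taken <- logical(nrow(gtBoxes))
    for (i in ord) {
        cand <- which(!taken & M[i, ] >= iouThreshold)
        if (length(cand) == 0L) next
        j <- cand[which.max(M[i, cand])]
        taken[j] <- TRUE
        match[i] <- j
    }
    match
}

#' Match detections to ground truth and count TP/FP/FN
#'
#' One-class (\code{"occ"}) mode: greedy one-to-one matching of detections
#' (confidence-descending) to per-worm unit boxes at IoU >= threshold;
#' matched detections are TP, unmatched detections FP, unmatched worms FN.
#' Multi-class (\code{"mcc"}) mode: detections are matched to group boxes
#' the same way; a class-n detection matched to an m-worm group credits
#' \code{min(n, m)} TP, \code{max(0, n - m)} FP and \code{max(0, m - n)} FN
#' (a class-2 detection of a 3-worm group counts 2 found worms and 1
#' missed); an unmatched detection adds its class to FP and an unmatched
#' group adds its size to FN. In both modes \code{tp + fn} equals the
#' ground-truth worm total.
#'
#' @param dets detection data.frame.
#' @param gt a \linkS4class{WormScene} or \code{list(unit = , group = )}.
#' @param mode \code{"occ"} or \code{"mcc"}.
#' @param iouThreshold matching threshold (default 0.5).
#' @return an \code{\link{evalCounts}} tally.
#' @export
matchAndCount <- function(dets, gt, mode = c("occ", "mcc"),
                          iouThreshold = 0.5) {
    mode <- match.arg(mode)
    .assertBoxes(dets, "dets")
    .assertScalarNum(iouThreshold, "iouThreshold", 0, 1)
    gt <- .asGroundTruth(gt)
    if (mode == "occ") {
        gtBoxes <- gt$unit
        m <- .greedyMatch(dets, gtBoxes, iouThreshold)
        tp <- sum(!is.na(m))
        evalCounts(tp = tp, fp = sum(is.na(m)), fn = nrow(gtBoxes) - tp)
    } else {
        gtBoxes <- gt$group
        m <- .greedyMatch(dets, gtBoxes, iouThreshold)
        cls <- if (is.null(dets$class)) rep(1L, nrow(dets)) else dets$class
        tp <- 0; fp <- 0; fn <- 0
        for (i in seq_len(nrow(dets))) {
            if (is.na(m[i])) fp <- fp + cls[i]
            else {
                sz <- gtBoxes$class[m[i]]
                tp <- tp + min(cls[i], sz)
                fp <- fp + max(0, cls[i] - sz)
                fn <- fn + max(0, sz - cls[i])
            }
        }
        unmatched <- setdiff(seq_len(nrow(gtBoxes)), m[!is.na(m)])
        fn <- fn + sum(gtBoxes$class[unmatched])
        evalCounts(tp = tp, fp = fp, fn = fn)
    }
}

#' Precision, recall and F1
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN); both are 1 when their
#' denominator is 0 (vacuous convention). F1 is the harmonic mean
#' 2pr/(p + r), 0 when p + r = 0.
#'
#' @param counts an \code{\link{evalCounts}} tally.
#' @return fraction in [0, 1].
#' @examples
#' detectionPrecision(evalCounts(tp = 91, fp = 9))   # 0.91
#' detectionRecall(evalCounts(tp = 93, fn = 7))      # 0.93
#' f1Score(0.91, 0.93)                               # about 0.92
#' @export
detectionPrecision <- function(counts) {
    stopifnot(inherits(counts, "EvalCounts"))
    d <- counts$tp + counts$fp
    if (d == 0) 1 else counts$tp / d
}

#' @rdname detectionPrecision
#' @export
detectionRecall <- function(counts) {
    stopifnot(inherits(counts, "EvalCounts"))
    d <- counts$tp + counts$fn
    if (d == 0) 1 else counts$tp / d
}

#' @rdname detectionPrecision
#' @param p,r precision and recall in [0, 1].
#' @export
f1Score <- function(p, r) {
    .assertScalarNum(p, "p", 0, 1)
    .assertScalarNum(r, "r", 0, 1)
    if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Precision-recall curve over descending confidence cutoffs
#'
#' Sweeps a cutoff over the distinct confidence values (descending); at
#' each cutoff the retained detections are re-matched with
#' \code{\link{matchAndCount}} and a (recall, precision) point is emitted.
#' Recall is non-decreasing along the sweep. Detections and ground truth
#' may be single objects or parallel lists (scene sets); counts are pooled
#' across scenes at each cutoff.
#'
#' @param dets detection data.frame with confidences, or a list of them.
#' @param gt matching ground truth (\linkS4class{WormScene} or
#'   \code{list(unit=, group=)}), or a parallel list.
#' @param mode \code{"occ"} or \code{"mcc"}.
#' @param iouThreshold matching threshold.
#' @return data.frame of class \code{PRCurve}: columns cutoff, recall,
#'   precision.
#' @export
prCurve <- function(dets, gt, mode = c("occ", "mcc"), iouThreshold = 0.5) {
    mode <- match.arg(mode)
    if (is.data.frame(dets)) { dets <- list(dets); gt <- list(gt) }
    stopifnot(length(dets) == length(gt))
    for (d in dets) .assertBoxes(d, "dets", needConfidence = TRUE)
    gt <- lapply(gt, .asGroundTruth)
    totalWorms <- sum(vapply(gt, function(g)
        if (!is.null(g$unit)) nrow(g$unit) else sum(g$group$class),
        numeric(1)))
    if (totalWorms == 0)
        stop("no ground-truth worms: recall is undefined", call. = FALSE)
    cutoffs <- sort(unique(unlist(lapply(dets, `[[`, "confidence"))),
                    decreasing = TRUE)
    out <- data.frame(cutoff = numeric(0), recall = numeric(0),
                      precision = numeric(0))
    for (ct in cutoffs) {
        tp <- 0; fp <- 0; fn <- 0
        for (s in seq_along(dets)) {
            cc <- matchAndCount(confidenceFilter(dets[[s]], ct), gt[[s]],
                                mode, iouThreshold)
            tp <- tp + cc$tp; fp <- fp + cc$fp; fn <- fn + cc$fn
        }
        c0 <- evalCounts(tp, fp, fn)
        out <- rbind(out, data.frame(cutoff = ct,
                                     recall = detectionRecall(c0),
                                     precision = detectionPrecision(c0)))
    }
    class(out) <- c("PRCurve", "data.frame")
    out
}

#' Average precision: step sum of precision over recall increments
#'
#' AP = sum_k (Recall_k - Recall_{k-1}) Precision_k with Recall_{-1} = 0,
#' taken directly over the curve points (no interpolation). An empty curve
#' (no detections) has zero recall mass and AP 0.
#'
#' @param curve a \code{\link{prCurve}} result (columns recall, precision).
#' @return fraction in [0, 1].
#' @examples
#' averagePrecision(data.frame(recall = c(0.5, 1), precision = c(1, 0.5)))
#' @export
averagePrecision <- function(curve) {
    if (!is.data.frame(curve) ||
        !all(c("recall", "precision") %in% names(curve)))
        stop("'curve' must have recall and precision columns", call. = FALSE)
    if (nrow(curve) == 0L) return(0)
    sum(diff(c(0, curve$recall)) * curve$precision)
}

#' Per-image detection error
#'
#' Number of detected worms minus ground truth; negative values are
#' undercounts. For the multi-class convention, detected worms are counted
#' after class division (sum of detection class labels).
#'
#' @param nDetected detected worm count (>= 0).
#' @param nGroundTruth true worm count (>= 0).
#' @return signed integer difference.
#' @examples
#' detectionError(38, 46)  # -8
#' detectionError(50, 46)  # +4
#' @export
detectionError <- function(nDetected, nGroundTruth) {
    .assertCount(nDetected, "nDetected") -
        .assertCount(nGroundTruth, "nGroundTruth")
}

#' Summarize per-image detection errors
#'
#' @param errors nonempty integer vector of per-image detection errors.
#' @return list of class \code{ErrorSummary}: the errors, their mean,
#'   sample (n - 1) standard deviation, and a unit-width histogram
#'   data.frame (error, count) spanning the observed range.
#' @export
summarizeErrors <- function(errors) {
    if (length(errors) == 0L || !is.numeric(errors) || any(!is.finite(errors)))
        stop("'errors' must be a nonempty vector of finite values",
             call. = FALSE)
    rng <- range(errors)
    bins <- seq(floor(rng[1]), ceiling(rng[2]))
    counts <- vapply(bins, function(b) sum(round(errors) == b), integer(1))
    structure(list(errors = errors, mean = mean(errors),
                   sd = if (length(errors) > 1) sd(errors) else 0,
                   histogram = data.frame(error = bins, count = counts)),
              class = "ErrorSummary")
}

#' @export
print.ErrorSummary <- function(x, ...) {
    cat(sprintf("ErrorSummary: n = %d, mean %+.2f, sd %.2f, range [%d, %d]\n",
                length(x$errors), x$mean, x$sd, min(x$errors),
                max(x$errors)))
    invisible(x)
}

#' Design arithmetic behind the four-class labelling
#'
#' How many worms fit a pond without overlapping, and how many classes an
#' overlap-aware detector therefore needs: a worm of length L fully
#' extended is the diagonal of its movement square (side L/sqrt(2), rounded
#' to 0.1 mm), the pond area over the movement area caps the non-overlap
#' capacity, and the maximum load over that capacity estimates how many
#' worms pile up.
#'
#' @param pondDiameter pond diameter in mm (default 5).
#' @param wormLength worm length in mm (default 1).
#' @param maxWorms maximum worms dropped into one pond (default 100).
#' @param piValue value of pi used in the pond-area product (default 3.14,
#'   the printed two-decimal convention).
#' @return list: pondArea (mm^2), movementSide (mm), movementArea (mm^2),
#'   capacity (worms, floored), overlapEstimate (worms, ceiling).
#' @examples
#' classDesign()  # 19.625 mm^2, 0.49 mm^2, 40 worms, 3 overlapped
#' @export
classDesign <- function(pondDiameter = 5, wormLength = 1, maxWorms = 100,
                        piValue = 3.14) {
    .assertScalarNum(pondDiameter, "pondDiameter", 1e-6)
    .assertScalarNum(wormLength, "wormLength", 1e-6)
    .assertCount(maxWorms, "maxWorms", 1L)
    pondArea <- piValue * (pondDiameter / 2)^2
    side <- round(wormLength / sqrt(2), 1)
    movementArea <- side^2
    capacity <- floor(pondArea / movementArea)
    list(pondArea = pondArea, movementSide = side,
         movementArea = movementArea, capacity = capacity,
         overlapEstimate = ceiling(maxWorms / capacity))
}
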