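# Fixtures and independent oracles shared across test files. Oracles are
# deliberately written from scratch (loops, no package internals) so they
# check the implementation rather than restate it.

testLibrary <- function(n = 12, seed = 123)
    makeShapeLibrary(n, seed = seed)

# hand-built straight horizontal worm: skeleton along x, half-width tapered
# at head and tail like the generator's profile
straightWorm <- function(length = 60, halfWidth = 2, intensity = 0.5,
                         y = 0) {
    xs <- seq(0, length, by = 1)
    s <- xs / length
    new("WormShape",
        skeleton = cbind(xs, rep(y, length(xs))),
        halfWidth = pmax(0.4, halfWidth * sin(pi * s)^0.35),
        intensity = intensity, posture = "wave")
}

# a scene assembled by hand (no generator) for targeted detector tests
manualScene <- function(unitBoxes, groupBoxes, width = 200, height = 150) {
    new("WormScene", image = matrix(1, width, height),
        unitBoxes = unitBoxes, groupBoxes = groupBoxes,
        pond = NULL, provenance = list())
}

# ring fixture for the circle Hough transform
ringImage <- function(width, height, cx, cy, r, halfThickness = 1.5) {
    xs <- 0:(width - 1); ys <- 0:(height - 1)
    dist <- sqrt(outer((xs - cx)^2, (ys - cy)^2, "+"))
    img <- matrix(0, width, height)
    img[abs(dist - r) < halfThickness] <- 1
    img
}

## -- independent IoU + greedy matcher + AP oracle ---------------------------

oracleIoU <- function(a, b) {
    ix1 <- max(a[1], b[1]); iy1 <- max(a[2], b[2])
    ix2 <- min(a[1] + a[3], b[1] + b[3]); iy2 <- min(a[2] + a[4], b[2] + b[4])
    if (ix2 <= ix1 || iy2 <= iy1) return(0)
    inter <- (ix2 - ix1) * (iy2 - iy1)
    inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# one-class matching at a confidence cutoff; returns c(tp, fp, fn)
oracleCountsAtCutoff <- function(dets, gtBoxes, cutoff, iouThr) {
    keep <- which(dets$confidence >= cutoff)
    keep <- keep[order(-dets$confidence[keep], keep)]
    used <- rep(FALSE, nrow(gtBoxes))
    tp <- 0
    for (i in keep) {
        bestJ <- 0; bestIoU <- -1
        for (j in seq_len(nrow(gtBoxes))) {
            if (used[j]) next
            v <- oracleIoU(as.numeric(dets[i, c("x", "y", "w", "h")]),
                           as.numeric(gtBoxes[j, c("x", "y", "w", "h")]))
            if (v >= iouThr && v > bestIoU) { bestIoU <- v; bestJ <- j }
        }
        if (bestJ > 0) { used[bestJ] <- TRUE; tp <- tp + 1 }
    }
    c(tp = tp, fp = length(keep) - tp, fn = nrow(gtBoxes) - tp)
}

# brute-force AP: enumerate every distinct confidence as a cutoff, compute
# precision/recall by re-matching, and apply the step sum with Recall_-1 = 0
oracleAveragePrecision <- function(dets, gtBoxes, iouThr = 0.5) {
    if (nrow(dets) == 0) return(0)
    cuts <- sort(unique(dets$confidence), decreasing = TRUE)
    prevRecall <- 0; ap <- 0
    for (ct in cuts) {
        n <- oracleCountsAtCutoff(dets, gtBoxes, ct, iouThr)
        prec <- if (n["tp"] + n["fp"] == 0) 1 else n["tp"] / (n["tp"] + n["fp"])
        rec <- if (n["tp"] + n["fn"] == 0) 1 else n["tp"] / (n["tp"] + n["fn"])
        ap <- ap + (rec - prevRecall) * prec
        prevRecall <- rec
    }
    unname(ap)
}

# random one-class toy instance: gt boxes on a grid, detections = jittered
# copies of some gt plus pure-noise boxes, distinct confidences
randomToyInstance <- function() {
    nGt <- sample(2:6, 1)
    gt <- wormBoxes(x = sample(0:150, nGt) , y = sample(0:150, nGt),
                    w = sample(10:25, nGt, TRUE),
                    h = sample(10:25, nGt, TRUE))
    hit <- sample(seq_len(nGt), sample(seq_len(nGt), 1))
    dx <- runif(length(hit), -2, 2)
    nFp <- sample(0:3, 1)
    dets <- rbind(
        data.frame(x = gt$x[hit] + dx, y = gt$y[hit] + dx,
                   w = gt$w[hit], h = gt$h[hit]),
        data.frame(x = runif(nFp, 200, 300), y = runif(nFp, 200, 300),
                   w = runif(nFp, 10, 25), h = runif(nFp, 10, 25)))
    dets$class <- 1L
    dets$confidence <- sample(seq(0.3, 0.99, by = 0.01), nrow(dets))
    dets
}

## -- independent CIoU oracle, term by term ----------------------------------

oracleCiou <- function(pred, gt) {
    px <- pred[1]; py <- pred[2]; pw <- pred[3]; ph <- pred[4]
    gx <- gt[1]; gy <- gt[2]; gw <- gt[3]; gh <- gt[4]
    iou <- oracleIoU(pred, gt)
    dcx <- (px + pw / 2) - (gx + gw / 2)
    dcy <- (py + ph / 2) - (gy + gh / 2)
    encW <- max(px + pw, gx + gw) - min(px, gx)
    encH <- max(py + ph, gy + gh) - min(py, gy)
    v <- 4 / pi^2 * (atan(gw / gh) - atan(pw / ph))^2
    alpha <- if (v == 0) 0 else v / (1 - iou + v)
    1 - iou + (dcx^2 + dcy^2) / (encW^2 + encH^2) + alpha * v
}

randomBox <- function() {
    c(runif(1, 0, 80), runif(1, 0, 80), runif(1, 2, 50), runif(1, 2, 50))
}
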