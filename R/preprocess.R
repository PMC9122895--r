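#' @include AllClasses.R boxes.R
NULL

## Pre-processing of raw pond photographs. The chain mirrors the standard
## background-correction recipe for stereomicroscope well images:
##   A  resized grayscale input
##   B  illumination estimate: grayscale closing (disc) + median filter
##   C  difference of Gaussians of B, emphasizing the pond rim
##   pond  circle Hough fit to C
##   D  A / B, with everything outside the pond filled with the mean of D
##      around the image periphery
## All images are numeric matrices indexed [x + 1, y + 1] (width x height),
## 0-based pixel coordinates, intensities in [0, 1] except D (ratio image,
## positive, unbounded above).

#' Default pre-processing configuration
#'
#' @param targetWidth,targetHeight working resolution in pixels; raw camera
#'   frames are downscaled to this size before any filtering.
#' @param diskDiameter diameter (odd, pixels) of the disc structuring element
#'   used by the closing; anything darker and smaller than the disc (a worm)
#'   is erased from the background estimate.
#' @param medianSize median filter window (odd, pixels; 1 disables).
#' @param dogSmall,dogLarge kernel sizes (pixels) of the two Gaussian blurs
#'   whose difference emphasizes the pond rim; sigma is (k - 1)/6 so the
#'   kernel spans about three standard deviations.
#' @param radiusRange numeric length-2: pond radii (pixels) searched by the
#'   circle Hough transform.
#' @param peripheryWidth thickness (pixels) of the four image-border strips
#'   whose mean ratio value fills the outside of the pond.
#' @param epsilon floor applied to the background estimate before division.
#' @param edgeQuantile fraction of pixels (by DoG magnitude) discarded before
#'   Hough voting; the strongest (1 - edgeQuantile) remain.
#' @param minVoteFrac minimum Hough support for a detected pond, as a
#'   fraction of the circle circumference.
#' @return a validated list of class \code{preprocessConfig}.
#' @export
preprocessConfig <- function(targetWidth = 704, targetHeight = 528,
                             diskDiameter = 25, medianSize = 3,
                             dogSmall = 20, dogLarge = 30,
                             radiusRange = c(100, 260),
                             peripheryWidth = 20, epsilon = 1 / 255,
                             edgeQuantile = 0.98, minVoteFrac = 0.2) {
    cfg <- list(targetWidth = .assertCount(targetWidth, "targetWidth", 1L),
                targetHeight = .assertCount(targetHeight, "targetHeight", 1L),
                diskDiameter = .assertCount(diskDiameter, "diskDiameter", 1L),
                medianSize = .assertCount(medianSize, "medianSize", 1L),
                dogSmall = .assertCount(dogSmall, "dogSmall", 1L),
                dogLarge = .assertCount(dogLarge, "dogLarge", 2L),
                radiusRange = as.numeric(radiusRange),
                peripheryWidth = .assertCount(peripheryWidth,
                                              "peripheryWidth", 1L),
                epsilon = .assertScalarNum(epsilon, "epsilon", 0, 1),
                edgeQuantile = .assertScalarNum(edgeQuantile, "edgeQuantile",
                                                0, 1),
                minVoteFrac = .assertScalarNum(minVoteFrac, "minVoteFrac",
                                               0, 1))
    if (cfg$dogSmall >= cfg$dogLarge)
        stop("'dogSmall' must be smaller than 'dogLarge'", call. = FALSE)
    if (length(cfg$radiusRange) != 2L ||
        cfg$radiusRange[1] >= cfg$radiusRange[2])
        stop("'radiusRange' must be c(rMin, rMax) with rMin < rMax",
             call. = FALSE)
    class(cfg) <- "preprocessConfig"
    cfg
}

#' Resize a raster and convert it to grayscale
#'
#' RGB input is reduced to luminance with ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B) before bilinear resizing, so a 2816 x 2112
#' camera frame becomes a 704 x 528 working image.
#'
#' @param image a file path (PNG/TIFF), an \code{EBImage::Image}, a numeric
#'   matrix (width x height) or a 3-D array (width x height x 3).
#' @param targetWidth,targetHeight output dimensions in pixels (>= 1).
#' @return numeric matrix \code{targetWidth x targetHeight} with values in
#'   [0, 1].
#' @export
resizeAndGray <- function(image, targetWidth = 704, targetHeight = 528) {
    .assertCount(targetWidth, "targetWidth", 1L)
    .assertCount(targetHeight, "targetHeight", 1L)
    if (is.character(image)) {
        if (!file.exists(image))
            stop("cannot read image: ", image, call. = FALSE)
        image <- EBImage::readImage(image)
    }
    arr <- unclass(if (is(image, "Image")) EBImage::imageData(image)
                   else image)
    if (length(dim(arr)) == 3L) {
        if (dim(arr)[3] < 3L) arr <- arr[, , 1]
        else arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] +
                    0.114 * arr[, , 3]
    }
    .assertGrayImage(arr, "image")
    if (max(arr) > 1) arr <- arr / 255   # 8-bit ingest
    if (nrow(arr) == targetWidth && ncol(arr) == targetHeight)
        return(arr)
    out <- EBImage::imageData(EBImage::resize(EBImage::Image(arr),
                                              w = targetWidth,
                                              h = targetHeight,
                                              filter = "bilinear"))
    pmin(pmax(matrix(out, targetWidth, targetHeight), 0), 1)
}

#' Estimate the image background (Image B)
#'
#' Grayscale morphological closing with a disc-shaped structuring element
#' erases dark features narrower than the disc (the worms), and a small
#' median filter removes residual speckle. The result is an illumination
#' estimate used as the divisor in \code{\link{backgroundCorrect}}.
#'
#' @param a grayscale matrix in [0, 1] (Image A).
#' @param diskDiameter odd disc diameter in pixels; worms at the working
#'   resolution are 3-8 px wide, well under the default 25.
#' @param medianSize odd median window in pixels (1 disables the median).
#' @return background matrix, same dimensions as \code{a}.
#' @export
estimateBackground <- function(a, diskDiameter = 25, medianSize = 3) {
    .assertGrayImage(a, "a")
    .assertCount(diskDiameter, "diskDiameter", 1L)
    .assertCount(medianSize, "medianSize", 1L)
    if (diskDiameter %% 2 == 0 || medianSize %% 2 == 0)
        stop("'diskDiameter' and 'medianSize' must be odd", call. = FALSE)
    if (diskDiameter > min(dim(a)))
        stop("'diskDiameter' exceeds the image size", call. = FALSE)
    closed <- EBImage::closing(a, EBImage::makeBrush(diskDiameter, "disc"))
    b <- matrix(EBImage::imageData(closed), nrow(a), ncol(a))
    if (medianSize > 1) {
        b <- pmin(pmax(b, 0), 1)   # medianFilter operates on [0, 1]
        b <- matrix(EBImage::imageData(
            EBImage::medianFilter(b, (medianSize - 1L) / 2L)),
            nrow(a), ncol(a))
    }
    b
}

#' Difference-of-Gaussians rim emphasis (Image C)
#'
#' Subtracts a wide Gaussian blur from a narrow one, leaving a signed
#' band-pass image whose zero crossing traces the pond rim. Kernel sizes k
#' map to sigma = (k - 1)/6 (three-sigma truncation). The default orientation
#' is small-minus-large; set \code{largeMinusSmall = TRUE} for the opposite
#' sign, which only flips the signed output and leaves the Hough stage
#' unchanged.
#'
#' @param b background matrix (Image B).
#' @param kSmall,kLarge Gaussian kernel sizes in pixels, kSmall < kLarge.
#' @param largeMinusSmall flip the sign of the output.
#' @return signed matrix, mean approximately 0 for large images.
#' @export
dogEdge <- function(b, kSmall = 20, kLarge = 30, largeMinusSmall = FALSE) {
    .assertGrayImage(b, "b")
    .assertCount(kSmall, "kSmall", 1L)
    .assertCount(kLarge, "kLarge", 1L)
    if (kSmall >= kLarge)
        stop("'kSmall' must be smaller than 'kLarge'", call. = FALSE)
    blur <- function(k) {
        s <- (k - 1) / 6
        if (s <= 0) return(b)
        matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(b),
                                                 sigma = s)),
               nrow(b), ncol(b))
    }
    d <- blur(kSmall) - blur(kLarge)
    if (largeMinusSmall) -d else d
}

#' Locate the pond rim with a circle Hough transform (vote accumulation)
#'
#' The strongest DoG-magnitude pixels vote for circle centres on a
#' coarse-to-fine grid; for each candidate centre, votes are binned by
#' integer radius inside \code{[rMin, rMax]} and the highest three-bin window
#' scores the centre. The winning circle is refined to the mean radius of its
#' supporting edge pixels.
#'
#' @param c signed DoG matrix (Image C).
#' @param rMin,rMax radius search range in pixels, rMin < rMax <= min(dim).
#' @param edgeQuantile quantile of |C| below which pixels do not vote.
#' @param minVoteFrac minimum support for a detection, as a fraction of the
#'   winning circle's circumference; below it the search fails.
#' @param maxEdgePoints cap on voting pixels (strongest kept) to bound cost.
#' @return a \linkS4class{PondGeometry}; centre and radius are recovered
#'   within about 2 px on clean synthetic rings.
#' @export
findPondEdge <- function(c, rMin, rMax, edgeQuantile = 0.98,
                         minVoteFrac = 0.2, maxEdgePoints = 15000L) {
    .assertGrayImage(c, "c")
    .assertScalarNum(rMin, "rMin", 1)
    .assertScalarNum(rMax, "rMax", rMin + 1)
    if (rMin >= rMax || rMax > min(dim(c)))
        stop("need rMin < rMax <= min(width, height)", call. = FALSE)
    mag <- abs(c)
    if (max(mag) < 1e-8)
        stop("pond not found: image has no edges", call. = FALSE)
    thr <- max(quantile(mag, edgeQuantile), 1e-8)
    idx <- which(mag >= thr)
    if (length(idx) > maxEdgePoints)
        idx <- idx[order(mag[idx], decreasing = TRUE)[seq_len(maxEdgePoints)]]
    ex <- (idx - 1L) %% nrow(c)          # 0-based x
    ey <- (idx - 1L) %/% nrow(c)         # 0-based y
    nb <- as.integer(floor(rMax) - ceiling(rMin) + 1L)
    r0 <- ceiling(rMin)

    scoreCenter <- function(cx, cy) {
        d <- round(sqrt((ex - cx)^2 + (ey - cy)^2))
        d <- d[d >= r0 & d <= floor(rMax)]
        if (length(d) == 0L) return(c(0, NA))
        v <- tabulate(d - r0 + 1L, nbins = nb)
        v3 <- v + c(0, v[-nb]) + c(v[-1], 0)   # three-bin window
        k <- which.max(v3)
        c(v3[k], r0 + k - 1L)
    }
    sweep <- function(xs, ys) {
        best <- c(-1, NA, NA, NA)
        for (cy in ys) for (cx in xs) {
            s <- scoreCenter(cx, cy)
            if (s[1] > best[1]) best <- c(s[1], cx, cy, s[2])
        }
        best
    }
    W <- nrow(c); H <- ncol(c)
    best <- sweep(seq(0, W - 1, by = 8), seq(0, H - 1, by = 8))
    for (step in c(2, 1)) {
        xs <- seq(max(0, best[2] - 4 * step), min(W - 1, best[2] + 4 * step),
                  by = step)
        ys <- seq(max(0, best[3] - 4 * step), min(H - 1, best[3] + 4 * step),
                  by = step)
        best <- sweep(xs, ys)
    }
    if (is.na(best[4]) || best[1] <= 0)
        stop("pond not found: no circle support in the radius range",
             call. = FALSE)
    d <- sqrt((ex - best[2])^2 + (ey - best[3])^2)
    support <- abs(d - best[4]) <= 1.5
    if (best[1] < minVoteFrac * 2 * pi * best[4] || !any(support))
        stop(sprintf(paste0("pond not found: best circle (centre %.0f, %.0f,",
                            " radius %.0f) has %d votes, below the minimum %.0f"),
                     best[2], best[3], best[4], as.integer(best[1]),
                     minVoteFrac * 2 * pi * best[4]), call. = FALSE)
    PondGeometry(best[2], best[3], mean(d[support]), votes = best[1])
}

#' Background-correct an image and mask outside the pond (Image D)
#'
#' Pixelwise division of the grayscale image by the background estimate
#' flattens the illumination (background ratio approximately 1.0, worms dark).
#' The mean ratio over the image periphery (four border strips, excluding
#' any pixels inside the pond) then replaces every pixel strictly outside
#' the pond circle; pixels inside the pond are exactly \code{a / b}.
#'
#' @param a grayscale matrix (Image A).
#' @param b background matrix (Image B), same dimensions.
#' @param pond a \linkS4class{PondGeometry}.
#' @param peripheryWidth border-strip thickness in pixels.
#' @param epsilon divisor floor.
#' @return ratio matrix (positive, unbounded above).
#' @export
backgroundCorrect <- function(a, b, pond, peripheryWidth = 20,
                              epsilon = 1 / 255) {
    .assertGrayImage(a, "a"); .assertGrayImage(b, "b")
    if (!identical(dim(a), dim(b)))
        stop("'a' and 'b' must have identical dimensions", call. = FALSE)
    stopifnot(is(pond, "PondGeometry"))
    .assertCount(peripheryWidth, "peripheryWidth", 1L)
    d <- a / pmax(b, epsilon)
    W <- nrow(d); H <- ncol(d)
    xs <- seq_len(W) - 1; ys <- seq_len(H) - 1
    dist2 <- outer((xs - pond@centerX)^2, (ys - pond@centerY)^2, "+")
    outside <- dist2 > pond@radius^2
    border <- matrix(FALSE, W, H)
    pw <- min(peripheryWidth, W, H)
    border[c(seq_len(pw), W - seq_len(pw) + 1L), ] <- TRUE
    border[, c(seq_len(pw), H - seq_len(pw) + 1L)] <- TRUE
    periphery <- border & outside
    if (!any(periphery)) periphery <- outside
    if (any(periphery)) d[outside] <- mean(d[periphery])
    d
}

#' Run the full pre-processing chain
#'
#' resize/grayscale, background estimation, DoG rim emphasis, circle
#' Hough pond detection, division-based correction and outside-pond fill.
#' Deterministic: two runs on the same input give identical arrays.
#'
#' @param image raw input accepted by \code{\link{resizeAndGray}}.
#' @param config a \code{\link{preprocessConfig}}.
#' @param keepStages also return the intermediate images A, B and C.
#' @return list with \code{image} (the corrected matrix D), \code{pond}
#'   (a \linkS4class{PondGeometry}) and, when \code{keepStages}, a
#'   \code{stages} list. Stage failures are re-signalled with the stage name
#'   attached.
#' @export
preprocessPipeline <- function(image, config = preprocessConfig(),
                               keepStages = FALSE) {
    stopifnot(inherits(config, "preprocessConfig"))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 call. = FALSE))
    }
    a <- stage("resize_and_gray",
               resizeAndGray(image, config$targetWidth, config$targetHeight))
    b <- stage("estimate_background",
               estimateBackground(a, config$diskDiameter, config$medianSize))
    cc <- stage("dog_edge", dogEdge(b, config$dogSmall, config$dogLarge))
    pond <- stage("find_pond_edge",
                  findPondEdge(cc, config$radiusRange[1],
                               config$radiusRange[2],
                               edgeQuantile = config$edgeQuantile,
                               minVoteFrac = config$minVoteFrac))
    d <- stage("background_correct",
               backgroundCorrect(a, b, pond, config$peripheryWidth,
                                 config$epsilon))
    out <- list(image = d, pond = pond)
    if (keepStages) out$stages <- list(A = a, B = b, C = cc)
    out
}

#' Write a corrected image to PNG (and an optional float sidecar)
#'
#' The ratio image is clipped to [0, 2] and mapped linearly to 8-bit
#' [0, 255] for the PNG; with \code{keepFloat} the lossless float64 matrix is
#' written alongside as \code{<path>.npy} (see \code{\link{writeNpy}}).
#'
#' @param d corrected ratio matrix (Image D).
#' @param path output PNG path.
#' @param keepFloat also write the NPY sidecar.
#' @return \code{path}, invisibly.
#' @export
writeCorrectedImage <- function(d, path, keepFloat = FALSE) {
    .assertGrayImage(d, "d")
    EBImage::writeImage(EBImage::Image(pmin(pmax(d, 0), 2) / 2), path)
    if (keepFloat) writeNpy(d, paste0(path, ".npy"))
    invisible(path)
}
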