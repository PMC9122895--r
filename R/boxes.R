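#' @include utils.R
NULL

## Bounding boxes are data.frames with columns x, y, w, h (pixels) and
## optionally class (integer >= 1) and confidence (in [0, 1]).
## Convention (used everywhere in the package): 0-based coordinates,
## x rightward, y downward, half-open extents [x, x+w) x [y, y+h).

#' Construct a bounding-box table
#'
#' @param x,y top-left corner in pixels (0-based).
#' @param w,h box width and height in pixels (> 0).
#' @param class integer class label (>= 1); for worm groups, the number of
#'   worms the box claims.
#' @param confidence optional detection confidence in [0, 1].
#' @return data.frame with columns x, y, w, h, class (and confidence when
#'   supplied).
#' @examples
#' wormBoxes(x = c(0, 10), y = c(0, 5), w = 4, h = 4, class = c(1, 3))
#' @export
wormBoxes <- function(x, y, w, h, class = 1L, confidence = NULL) {
    df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                     w = as.numeric(w), h = as.numeric(h))
    df$class <- if (nrow(df)) as.integer(class) else integer(0)
    if (!is.null(confidence))
        df$confidence <- if (nrow(df)) as.numeric(confidence) else numeric(0)
    .assertBoxes(df)
    df
}

.assertBoxes <- function(df, name = "boxes", needConfidence = FALSE) {
    need <- c("x", "y", "w", "h")
    if (!is.data.frame(df) || !all(need %in% names(df)))
        stop(sprintf("'%s' must be a data.frame with columns x, y, w, h",
                     name), call. = FALSE)
    if (nrow(df) > 0) {
        if (any(df$w <= 0) || any(df$h <= 0))
            stop(sprintf("'%s': box widths and heights must be > 0", name),
                 call. = FALSE)
        if (!is.null(df$class) && any(df$class < 1))
            stop(sprintf("'%s': class labels must be >= 1", name),
                 call. = FALSE)
        if (!is.null(df$confidence) &&
            (any(df$confidence < 0) || any(df$confidence > 1)))
            stop(sprintf("'%s': confidences must lie in [0, 1]", name),
                 call. = FALSE)
    }
    if (needConfidence && is.null(df$confidence))
        stop(sprintf("'%s' must carry a 'confidence' column", name),
             call. = FALSE)
    invisible(df)
}

## minimal box containing every box in df (one-row data.frame)
.boxUnion <- function(df) {
    x0 <- min(df$x); y0 <- min(df$y)
    data.frame(x = x0, y = y0,
               w = max(df$x + df$w) - x0, h = max(df$y + df$h) - y0)
}

#' Intersection-over-union of two boxes
#'
#' Area of overlap divided by area of union under the half-open pixel
#' convention. Symmetric; 0 for disjoint boxes, 1 for identical boxes.
#'
#' @param a,b boxes: numeric vectors \code{c(x, y, w, h)} or one-row
#'   data.frames with those columns.
#' @return fraction in [0, 1].
#' @examples
#' boxIoU(c(0, 0, 2, 2), c(1, 1, 2, 2))  # 1/7
#' @export
boxIoU <- function(a, b) {
    a <- .asBoxVec(a); b <- .asBoxVec(b)
    iw <- min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1])
    ih <- min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2])
    if (iw <= 0 || ih <= 0) return(0)
    inter <- iw * ih
    inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

.asBoxVec <- function(b) {
    if (is.data.frame(b)) b <- as.numeric(b[1, c("x", "y", "w", "h")])
    if (length(b) != 4L || any(!is.finite(b)) || b[3] <= 0 || b[4] <= 0)
        stop("a box must be (x, y, w, h) with w, h > 0", call. = FALSE)
    b
}

#' Pairwise IoU matrix between two box tables
#'
#' @param a,b box data.frames (columns x, y, w, h).
#' @return \code{nrow(a)} x \code{nrow(b)} matrix of IoU values.
#' @export
iouMatrix <- function(a, b) {
    .assertBoxes(a, "a"); .assertBoxes(b, "b")
    if (nrow(a) == 0L || nrow(b) == 0L)
        return(matrix(numeric(0), nrow(a), nrow(b)))
    ax2 <- a$x + a$w; ay2 <- a$y + a$h
    bx2 <- b$x + b$w; by2 <- b$y + b$h
    iw <- pmax(0, outer(ax2, bx2, pmin) - outer(a$x, b$x, pmax))
    ih <- pmax(0, outer(ay2, by2, pmin) - outer(a$y, b$y, pmax))
    inter <- iw * ih
    un <- outer(a$w * a$h, b$w * b$h, "+") - inter
    inter / un
}
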