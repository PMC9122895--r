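#' @include utils.R
NULL

setClassUnion("PondGeometryOrNULL", "NULL")

#' PondGeometry: a detected circular pond
#'
#' Circle parameters (centre and radius, in pixels, 0-based image
#' coordinates) returned by \code{\link{findPondEdge}}.
#'
#' @slot centerX,centerY circle centre in pixels (x rightward, y downward).
#' @slot radius circle radius in pixels, > 0.
#' @slot votes Hough accumulator support for the winning circle (edge-pixel
#'   count); 0 when constructed by hand.
#' @export
setClass("PondGeometry",
    representation(centerX = "numeric", centerY = "numeric",
                   radius = "numeric", votes = "numeric"),
    prototype(votes = 0))

setValidity("PondGeometry", function(object) {
    msg <- NULL
    for (s in c("centerX", "centerY", "radius", "votes"))
        if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
            msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
    if (is.null(msg) && object@radius <= 0)
        msg <- c(msg, "'radius' must be > 0")
    if (is.null(msg)) TRUE else msg
})

setIs("PondGeometry", "PondGeometryOrNULL")

#' Construct a PondGeometry
#'
#' @param centerX,centerY circle centre in pixels.
#' @param radius circle radius in pixels (> 0).
#' @param votes optional accumulator support.
#' @return a \linkS4class{PondGeometry}.
#' @examples
#' PondGeometry(352, 264, 200)
#' @export
PondGeometry <- function(centerX, centerY, radius, votes = 0) {
    new("PondGeometry", centerX = as.numeric(centerX),
        centerY = as.numeric(centerY), radius = as.numeric(radius),
        votes = as.numeric(votes))
}

#' WormShape: a procedural worm body
#'
#' A worm is modelled as an open (wave, omega) or self-crossing (coil)
#' skeleton polyline with a tapered half-width profile and a darkness level
#' relative to the flat background of a corrected image.
#'
#' @slot skeleton n x 2 matrix of skeleton points in pixels; consecutive
#'   points are closer than 5 px.
#' @slot halfWidth per-point stroke half-width in pixels, all > 0.
#' @slot intensity darkness in [0, 1]: rendered stroke value is about
#'   1 - intensity on a background of 1.
#' @slot posture one of "wave", "omega", "coil".
#' @export
setClass("WormShape",
    representation(skeleton = "matrix", halfWidth = "numeric",
                   intensity = "numeric", posture = "character"))

setValidity("WormShape", function(object) {
    sk <- object@skeleton
    msg <- NULL
    if (!is.numeric(sk) || ncol(sk) != 2L || nrow(sk) < 8L)
        msg <- c(msg, "skeleton must be a numeric matrix with >= 8 rows and 2 columns")
    else {
        gaps <- sqrt(rowSums(diff(sk)^2))
        if (any(gaps >= 5)) msg <- c(msg, "consecutive skeleton points must be < 5 px apart")
        if (length(object@halfWidth) != nrow(sk))
            msg <- c(msg, "halfWidth must have one value per skeleton point")
    }
    if (any(object@halfWidth <= 0)) msg <- c(msg, "half-widths must be > 0")
    if (length(object@intensity) != 1L || object@intensity < 0 ||
        object@intensity > 1)
        msg <- c(msg, "intensity must be a scalar in [0, 1]")
    if (!object@posture %in% c("wave", "omega", "coil"))
        msg <- c(msg, "posture must be 'wave', 'omega' or 'coil'")
    if (is.null(msg)) TRUE else msg
})

#' WormPatch: a rendered model image of 1-4 overlapping worms
#'
#' The synthetic analogue of a manually cropped model sub-image: a small
#' grayscale patch (background about 1.0, dark worm strokes) with per-worm
#' tight bounding boxes and the minimal group box that encloses them. A patch
#' holding n worms carries class label n in the multi-class convention.
#'
#' @slot patch numeric matrix, width x height indexing (\code{patch[x+1, y+1]}).
#' @slot nWorms number of worms (1..4 by default conventions).
#' @slot unitBoxes data.frame of per-worm boxes (x, y, w, h, class = 1).
#' @slot groupBox one-row data.frame: minimal box containing all unit boxes,
#'   class = nWorms.
#' @export
setClass("WormPatch",
    representation(patch = "matrix", nWorms = "integer",
                   unitBoxes = "data.frame", groupBox = "data.frame"))

setValidity("WormPatch", function(object) {
    msg <- NULL
    u <- object@unitBoxes; g <- object@groupBox
    if (object@nWorms != nrow(u))
        msg <- c(msg, "nWorms must equal the number of unit boxes")
    if (nrow(g) != 1L) msg <- c(msg, "groupBox must have exactly one row")
    if (nrow(u) > 0 && nrow(g) == 1L) {
        un <- .boxUnion(u)
        if (!isTRUE(all.equal(as.numeric(un[c("x", "y", "w", "h")]),
                              as.numeric(g[c("x", "y", "w", "h")]))))
            msg <- c(msg, "groupBox must be the minimal box containing the unit boxes")
        W <- nrow(object@patch); H <- ncol(object@patch)
        if (any(u$x < 0 | u$y < 0 | u$x + u$w > W | u$y + u$h > H))
            msg <- c(msg, "unit boxes must lie within the patch")
    }
    if (is.null(msg)) TRUE else msg
})

#' WormScene: a simulated microscope field with ground truth
#'
#' A full-size corrected-image lookalike onto which worm groups
#' (\linkS4class{WormPatch}es) have been placed, carrying ground truth at two
#' granularities: \code{unitBoxes} (one class-1 box per worm, the one-class
#' convention) and \code{groupBoxes} (one class-n box per n-worm group, the
#' multi-class convention). Worm count is conserved:
#' \code{sum(groupBoxes$class) == nrow(unitBoxes)}.
#'
#' @slot image numeric matrix (width x height).
#' @slot unitBoxes data.frame x, y, w, h, class (all 1), group (group index).
#' @slot groupBoxes data.frame x, y, w, h, class (worms in group).
#' @slot pond \linkS4class{PondGeometry} of the drawn pond disk, or NULL.
#' @slot provenance list of the seed and generator parameters used.
#' @export
setClass("WormScene",
    representation(image = "matrix", unitBoxes = "data.frame",
                   groupBoxes = "data.frame", pond = "PondGeometryOrNULL",
                   provenance = "list"))

setValidity("WormScene", function(object) {
    msg <- NULL
    u <- object@unitBoxes; g <- object@groupBoxes
    if (sum(g$class) != nrow(u))
        msg <- c(msg, "worm count not conserved: sum(group classes) != number of unit boxes")
    W <- nrow(object@image); H <- ncol(object@image)
    for (b in list(u, g))
        if (nrow(b) > 0 && any(b$x < 0 | b$y < 0 | b$x + b$w > W | b$y + b$h > H))
            msg <- c(msg, "ground-truth boxes must lie within the image frame")
    if (is.null(msg)) TRUE else msg
})
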