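#' @include AllClasses.R
NULL

#' Accessors for scene and patch objects
#'
#' \code{sceneImage} returns the pixel matrix; \code{unitBoxes} the per-worm
#' (class-1) ground truth; \code{groupBoxes} the per-group (class-n) ground
#' truth; \code{nWorms} the total worm count; \code{pondGeometry} the drawn
#' pond circle (or NULL).
#'
#' @param object a \linkS4class{WormScene} or \linkS4class{WormPatch}.
#' @return matrix, data.frame, integer or \linkS4class{PondGeometry} as
#'   appropriate.
#' @name scene-accessors
NULL

#' @rdname scene-accessors
#' @export
setGeneric("sceneImage", function(object) standardGeneric("sceneImage"))
#' @rdname scene-accessors
#' @export
setGeneric("unitBoxes", function(object) standardGeneric("unitBoxes"))
#' @rdname scene-accessors
#' @export
setGeneric("groupBoxes", function(object) standardGeneric("groupBoxes"))
#' @rdname scene-accessors
#' @export
setGeneric("nWorms", function(object) standardGeneric("nWorms"))
#' @rdname scene-accessors
#' @export
setGeneric("pondGeometry", function(object) standardGeneric("pondGeometry"))

#' @rdname scene-accessors
setMethod("sceneImage", "WormScene", function(object) object@image)
#' @rdname scene-accessors
setMethod("sceneImage", "WormPatch", function(object) object@patch)
#' @rdname scene-accessors
setMethod("unitBoxes", "WormScene", function(object) object@unitBoxes)
#' @rdname scene-accessors
setMethod("unitBoxes", "WormPatch", function(object) object@unitBoxes)
#' @rdname scene-accessors
setMethod("groupBoxes", "WormScene", function(object) object@groupBoxes)
#' @rdname scene-accessors
setMethod("groupBoxes", "WormPatch", function(object) object@groupBox)
#' @rdname scene-accessors
setMethod("nWorms", "WormScene", function(object) nrow(object@unitBoxes))
#' @rdname scene-accessors
setMethod("nWorms", "WormPatch", function(object) as.integer(object@nWorms))
#' @rdname scene-accessors
setMethod("pondGeometry", "WormScene", function(object) object@pond)

setMethod("show", "PondGeometry", function(object) {
    cat(sprintf("PondGeometry: centre (%.1f, %.1f) px, radius %.1f px, votes %d\n",
                object@centerX, object@centerY, object@radius,
                as.integer(object@votes)))
})

setMethod("show", "WormShape", function(object) {
    len <- sum(sqrt(rowSums(diff(object@skeleton)^2)))
    cat(sprintf("WormShape (%s): %d skeleton points, arclength %.1f px, max half-width %.2f px\n",
                object@posture, nrow(object@skeleton), len,
                max(object@halfWidth)))
})

setMethod("show", "WormPatch", function(object) {
    cat(sprintf("WormPatch: %dx%d px, %d worm(s), group box [%d, %d, %d, %d]\n",
                nrow(object@patch), ncol(object@patch), object@nWorms,
                object@groupBox$x, object@groupBox$y,
                object@groupBox$w, object@groupBox$h))
})

setMethod("show", "WormScene", function(object) {
    cat(sprintf("WormScene: %dx%d px, %d worms in %d groups",
                nrow(object@image), ncol(object@image),
                nrow(object@unitBoxes), nrow(object@groupBoxes)))
    if (!is.null(object@pond)) cat(" (pond drawn)")
    cat("\n")
    tab <- table(factor(object@groupBoxes$class, levels = seq_len(max(
        c(1, object@groupBoxes$class)))))
    cat("  group classes:",
        paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
})
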