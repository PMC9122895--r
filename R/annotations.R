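#' @include boxes.R
NULL

#' Write and read Darknet TXT annotations
#'
#' One line per box: \code{class_index x_center y_center width height}, all
#' normalized to [0, 1] by the image dimensions, space-separated, class index
#' 0-based (Class 1 is written as 0). One TXT file per image, same stem.
#'
#' @param boxes box data.frame (x, y, w, h, class).
#' @param path TXT file path.
#' @param imageWidth,imageHeight image dimensions in pixels, used for
#'   normalization.
#' @return \code{path} (write) or a box data.frame (read). Denormalized
#'   coordinates round-trip within 0.5 px.
#' @export
writeDarknetBoxes <- function(boxes, path, imageWidth, imageHeight) {
    .assertBoxes(boxes)
    .assertCount(imageWidth, "imageWidth", 1L)
    .assertCount(imageHeight, "imageHeight", 1L)
    cls <- if (is.null(boxes$class)) rep(1L, nrow(boxes)) else boxes$class
    lines <- sprintf("%d %.6f %.6f %.6f %.6f", cls - 1L,
                     (boxes$x + boxes$w / 2) / imageWidth,
                     (boxes$y + boxes$h / 2) / imageHeight,
                     boxes$w / imageWidth, boxes$h / imageHeight)
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeDarknetBoxes
#' @export
readDarknetBoxes <- function(path, imageWidth, imageHeight) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
        return(wormBoxes(numeric(0), numeric(0), numeric(0), numeric(0),
                         integer(0)))
    m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
    if (ncol(m) != 5L) stop("malformed Darknet annotation: ", path,
                            call. = FALSE)
    w <- m[, 4] * imageWidth; h <- m[, 5] * imageHeight
    wormBoxes(x = m[, 2] * imageWidth - w / 2,
              y = m[, 3] * imageHeight - h / 2,
              w = w, h = h, class = as.integer(m[, 1]) + 1L)
}

#' Write and read the JSON annotation dialect
#'
#' Top-left integer-pixel convention:
#' \code{{"image", "width", "height", "granularity", "boxes": [{"x","y","w","h","class"}]}}
#' with granularity \code{"unit"} (one class-1 box per worm) or
#' \code{"group"} (one class-n box per n-worm group). Integer coordinates
#' round-trip bit-exactly.
#'
#' @param boxes box data.frame.
#' @param path JSON file path.
#' @param image image file name the annotation refers to.
#' @param imageWidth,imageHeight image dimensions in pixels.
#' @param granularity \code{"unit"} or \code{"group"}.
#' @return \code{path} (write); a list with fields \code{image}, \code{width},
#'   \code{height}, \code{granularity} and \code{boxes} (read).
#' @export
writeBoxesJSON <- function(boxes, path, image, imageWidth, imageHeight,
                           granularity = c("unit", "group")) {
    .assertBoxes(boxes)
    granularity <- match.arg(granularity)
    blist <- lapply(seq_len(nrow(boxes)), function(i) list(
        x = as.integer(round(boxes$x[i])), y = as.integer(round(boxes$y[i])),
        w = as.integer(round(boxes$w[i])), h = as.integer(round(boxes$h[i])),
        class = as.integer(boxes$class[i])))
    obj <- list(image = image, width = as.integer(imageWidth),
                height = as.integer(imageHeight), granularity = granularity,
                boxes = blist)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeBoxesJSON
#' @export
readBoxesJSON <- function(path) {
    obj <- jsonlite::read_json(path)
    b <- obj$boxes
    boxes <- if (length(b) == 0L)
        wormBoxes(numeric(0), numeric(0), numeric(0), numeric(0), integer(0))
    else
        wormBoxes(x = vapply(b, `[[`, 0, "x"), y = vapply(b, `[[`, 0, "y"),
                  w = vapply(b, `[[`, 0, "w"), h = vapply(b, `[[`, 0, "h"),
                  class = vapply(b, `[[`, 0, "class"))
    list(image = obj$image, width = obj$width, height = obj$height,
         granularity = obj$granularity, boxes = boxes)
}

#' Write and read detection JSON
#'
#' Serialization of detector output:
#' \code{{"image", "detections": [{"x","y","w","h","class","confidence"}]}}.
#'
#' @param dets detection data.frame (x, y, w, h, class, confidence).
#' @param path JSON file path.
#' @param image image file name.
#' @return \code{path} (write); a list with \code{image} and a detection
#'   data.frame \code{detections} (read).
#' @export
writeDetectionsJSON <- function(dets, path, image = "") {
    .assertBoxes(dets, "dets", needConfidence = TRUE)
    dlist <- lapply(seq_len(nrow(dets)), function(i) list(
        x = dets$x[i], y = dets$y[i], w = dets$w[i], h = dets$h[i],
        class = as.integer(dets$class[i]), confidence = dets$confidence[i]))
    jsonlite::write_json(list(image = image, detections = dlist), path,
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeDetectionsJSON
#' @export
readDetectionsJSON <- function(path) {
    obj <- jsonlite::read_json(path)
    d <- obj$detections
    dets <- if (length(d) == 0L)
        wormBoxes(numeric(0), numeric(0), numeric(0), numeric(0), integer(0),
                  numeric(0))
    else
        wormBoxes(x = vapply(d, `[[`, 0, "x"), y = vapply(d, `[[`, 0, "y"),
                  w = vapply(d, `[[`, 0, "w"), h = vapply(d, `[[`, 0, "h"),
                  class = vapply(d, `[[`, 0, "class"),
                  confidence = vapply(d, `[[`, 0, "confidence"))
    list(image = obj$image, detections = dets)
}
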