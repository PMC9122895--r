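#' @include AllClasses.R boxes.R annotations.R
NULL

## Procedural stand-in for a library of manually cropped worm sub-images.
## Adult C. elegans are ~1 mm long; at the working resolution a 5-mm pond
## spans roughly 450 px, so a worm is 50-90 px long and 4-6 px wide. Bodies
## take wave, omega and coil postures; a coil self-crosses.

#' Parameters of the procedural worm-shape model
#'
#' @param lengthRange worm arclength range in pixels (about 1 mm at the
#'   working scale of roughly 90 px/mm).
#' @param halfWidthRange mid-body stroke half-width range in pixels.
#' @param intensityRange darkness range in [0, 1] relative to the flat
#'   background of a corrected image.
#' @param postureWeights sampling weights for the wave, omega and coil
#'   posture modes (named numeric, any positive scale).
#' @param step skeleton sampling step in pixels (< 5 preserves continuity).
#' @param waveAmpRange,waveFreqRange heading-angle amplitude (radians) and
#'   number of body waves for the wave posture.
#' @param omegaTurnRange total body turn (radians) for the omega posture;
#'   below a full turn, so the body stays open.
#' @param coilTurnRange total body turn (radians) for the coil posture;
#'   beyond a full turn, so the body crosses itself.
#' @return a validated list of class \code{wormShapeParams}.
#' @export
wormShapeParams <- function(lengthRange = c(50, 90),
                            halfWidthRange = c(1.8, 2.8),
                            intensityRange = c(0.35, 0.6),
                            postureWeights = c(wave = 0.5, omega = 0.3,
                                               coil = 0.2),
                            step = 1.2,
                            waveAmpRange = c(0.5, 1.1),
                            waveFreqRange = c(1, 2.2),
                            omegaTurnRange = c(1.2 * pi, 1.7 * pi),
                            coilTurnRange = c(2.4 * pi, 3.2 * pi)) {
    p <- list(lengthRange = as.numeric(lengthRange),
              halfWidthRange = as.numeric(halfWidthRange),
              intensityRange = as.numeric(intensityRange),
              postureWeights = postureWeights, step = as.numeric(step),
              waveAmpRange = as.numeric(waveAmpRange),
              waveFreqRange = as.numeric(waveFreqRange),
              omegaTurnRange = as.numeric(omegaTurnRange),
              coilTurnRange = as.numeric(coilTurnRange))
    for (nm in grep("Range$", names(p), value = TRUE)) {
        r <- p[[nm]]
        if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] <= 0)
            stop(sprintf("'%s' must be a positive, ordered range", nm),
                 call. = FALSE)
    }
    if (!all(c("wave", "omega", "coil") %in% names(p$postureWeights)) ||
        any(p$postureWeights < 0) || sum(p$postureWeights) <= 0)
        stop("'postureWeights' needs nonnegative wave/omega/coil weights",
             call. = FALSE)
    if (p$step <= 0 || p$step >= 5)
        stop("'step' must lie in (0, 5) to keep the skeleton continuous",
             call. = FALSE)
    class(p) <- "wormShapeParams"
    p
}

#' Draw one procedural worm shape
#'
#' Integrates a heading-angle profile over arclength: sinusoidal for the
#' wave posture, a partial turn for omega, and more than a full turn (with a
#' radial wobble) for coil, which therefore self-crosses. The half-width
#' profile tapers towards head and tail. Uses the current RNG state, so
#' results are reproducible under \code{set.seed}.
#'
#' @param params a \code{\link{wormShapeParams}}.
#' @return a \linkS4class{WormShape}.
#' @examples
#' set.seed(1)
#' makeWormShape(wormShapeParams())
#' @export
makeWormShape <- function(params = wormShapeParams()) {
    stopifnot(inherits(params, "wormShapeParams"))
    runifR <- function(r) runif(1, r[1], r[2])
    L <- runifR(params$lengthRange)
    n <- max(8L, as.integer(ceiling(L / params$step)) + 1L)
    s <- seq(0, 1, length.out = n)            # normalized arclength
    ds <- L / (n - 1)
    posture <- sample(c("wave", "omega", "coil"), 1L,
                      prob = params$postureWeights[c("wave", "omega",
                                                     "coil")])
    theta0 <- runif(1, 0, 2 * pi)
    for (try in seq_len(20L)) {
        theta <- switch(posture,
            wave = theta0 + runifR(params$waveAmpRange) *
                sin(2 * pi * runifR(params$waveFreqRange) * s +
                    runif(1, 0, 2 * pi)),
            omega = theta0 + sample(c(-1, 1), 1) *
                runifR(params$omegaTurnRange) * s +
                0.15 * sin(2 * pi * s + runif(1, 0, 2 * pi)),
            coil = theta0 + sample(c(-1, 1), 1) *
                runifR(params$coilTurnRange) * s +
                0.35 * sin(4 * pi * s + runif(1, 0, 2 * pi)))
        sk <- cbind(cumsum(cos(theta)) * ds, cumsum(sin(theta)) * ds)
        sk <- sweep(sk, 2, colMeans(sk))
        hw <- pmax(0.4, runifR(params$halfWidthRange) *
                        sin(pi * s)^0.35)
        shape <- new("WormShape", skeleton = sk, halfWidth = hw,
                     intensity = runifR(params$intensityRange),
                     posture = posture)
        if (posture != "coil" || shapeSelfIntersects(shape)) return(shape)
    }
    stop("failed to draw a self-crossing coil; widen 'coilTurnRange'",
         call. = FALSE)
}

#' Does a worm skeleton cross itself?
#'
#' Proper segment-pair intersection test over non-adjacent skeleton
#' segments; TRUE for coil postures by construction.
#'
#' @param shape a \linkS4class{WormShape}.
#' @return logical.
#' @export
shapeSelfIntersects <- function(shape) {
    stopifnot(is(shape, "WormShape"))
    p <- shape@skeleton
    n <- nrow(p) - 1L
    cross2 <- function(ox, oy, ax, ay, bx, by)
        (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
    for (i in seq_len(n - 2L)) {
        j <- seq.int(i + 2L, n)
        d1 <- cross2(p[i, 1], p[i, 2], p[i + 1, 1], p[i + 1, 2],
                     p[j, 1], p[j, 2])
        d2 <- cross2(p[i, 1], p[i, 2], p[i + 1, 1], p[i + 1, 2],
                     p[j + 1, 1], p[j + 1, 2])
        d3 <- cross2(p[j, 1], p[j, 2], p[j + 1, 1], p[j + 1, 2],
                     p[i, 1], p[i, 2])
        d4 <- cross2(p[j, 1], p[j, 2], p[j + 1, 1], p[j + 1, 2],
                     p[i + 1, 1], p[i + 1, 2])
        if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
    }
    FALSE
}

#' Draw a library of worm shapes
#'
#' @param n library size.
#' @param params a \code{\link{wormShapeParams}}.
#' @param seed optional seed (caller RNG state is restored).
#' @return list of \linkS4class{WormShape}s.
#' @export
makeShapeLibrary <- function(n, params = wormShapeParams(), seed = NULL) {
    .assertCount(n, "n", 1L)
    .withSeed(seed, replicate(n, makeWormShape(params), simplify = FALSE))
}

#' Rotate, zoom and translate a worm shape
#'
#' Rotation is about the skeleton centroid; zoom scales both the skeleton
#' and the half-width profile.
#'
#' @param shape a \linkS4class{WormShape}.
#' @param rotation rotation in degrees.
#' @param zoom scale factor (> 0).
#' @param offset length-2 translation in pixels.
#' @return transformed \linkS4class{WormShape}.
#' @export
transformShape <- function(shape, rotation = 0, zoom = 1, offset = c(0, 0)) {
    stopifnot(is(shape, "WormShape"))
    .assertScalarNum(zoom, "zoom", lower = 1e-3)
    a <- rotation * pi / 180
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    sk <- shape@skeleton
    ctr <- colMeans(sk)
    sk <- sweep(sk, 2, ctr) %*% t(R) * zoom
    sk <- sweep(sk, 2, ctr + as.numeric(offset), "+")
    new("WormShape", skeleton = sk, halfWidth = shape@halfWidth * zoom,
        intensity = shape@intensity, posture = shape@posture)
}

## stroke extent of a shape: skeleton range padded by local half-width
.shapeBounds <- function(shape) {
    sk <- shape@skeleton; hw <- shape@halfWidth
    c(xmin = min(sk[, 1] - hw), xmax = max(sk[, 1] + hw),
      ymin = min(sk[, 2] - hw), ymax = max(sk[, 2] + hw))
}

## Rasterize one shape into (darkness, core mask) on a patch grid.
## Pixel centres sit at integer coordinates; the soft edge spans ~1 px.
.rasterizeShape <- function(shape, W, H) {
    b <- .shapeBounds(shape)
    x0 <- max(0L, as.integer(floor(b["xmin"] - 1)))
    x1 <- min(W - 1L, as.integer(ceiling(b["xmax"] + 1)))
    y0 <- max(0L, as.integer(floor(b["ymin"] - 1)))
    y1 <- min(H - 1L, as.integer(ceiling(b["ymax"] + 1)))
    if (x1 < x0 || y1 < y0)
        stop("shape lies outside the patch", call. = FALSE)
    gx <- x0:x1; gy <- y0:y1
    sk <- shape@skeleton; hw <- shape@halfWidth
    dx2 <- outer(gx, sk[, 1], "-")^2          # |gx| x npts
    dy2 <- outer(gy, sk[, 2], "-")^2          # |gy| x npts
    best <- matrix(Inf, length(gx), length(gy))
    bestHw <- matrix(hw[1], length(gx), length(gy))
    for (k in seq_len(nrow(sk))) {
        d2 <- outer(dx2[, k], dy2[, k], "+")
        upd <- d2 < best
        if (any(upd)) {
            best[upd] <- d2[upd]
            bestHw[upd] <- hw[k]
        }
    }
    dist <- sqrt(best)
    alpha <- pmin(pmax(bestHw + 0.5 - dist, 0), 1)
    core <- dist <= pmax(bestHw, 0.8)
    list(gx = gx, gy = gy, darkness = shape@intensity * alpha, core = core)
}

## tight integer box of a logical mask defined on grid gx x gy
.maskBox <- function(core, gx, gy) {
    cx <- which(rowSums(core) > 0); cy <- which(colSums(core) > 0)
    if (length(cx) == 0L)
        stop("shape rendered to an empty mask", call. = FALSE)
    data.frame(x = gx[min(cx)], y = gy[min(cy)],
               w = gx[max(cx)] - gx[min(cx)] + 1L,
               h = gy[max(cy)] - gy[min(cy)] + 1L)
}

#' Render worm shapes into a model image
#'
#' Draws the shapes as dark, soft-edged strokes on a background of 1.0,
#' centring the group in the patch; crossings darken multiplicatively.
#' Per-worm tight bounding boxes are measured from the rendered stroke
#' masks, and the group box is their minimal enclosing box.
#'
#' @param shapes list of 1-4 \linkS4class{WormShape}s (relative placement is
#'   taken from their coordinates; the group is recentred jointly).
#' @param patchSize patch side length in pixels (default 100).
#' @param noiseSd additive Gaussian noise standard deviation (0 disables).
#' @return a \linkS4class{WormPatch} with \code{nWorms == length(shapes)}.
#' @export
renderModelImage <- function(shapes, patchSize = 100, noiseSd = 0.02) {
    if (!is.list(shapes) || length(shapes) < 1L)
        stop("'shapes' must be a nonempty list of WormShape objects",
             call. = FALSE)
    if (length(shapes) > 4L)
        stop("at most 4 worms per model image", call. = FALSE)
    patchSize <- .assertCount(patchSize, "patchSize", 8L)
    .assertScalarNum(noiseSd, "noiseSd", 0)
    lapply(shapes, function(s) stopifnot(is(s, "WormShape")))
    bounds <- vapply(shapes, .shapeBounds, numeric(4))
    lo <- c(min(bounds["xmin", ]), min(bounds["ymin", ]))
    hi <- c(max(bounds["xmax", ]), max(bounds["ymax", ]))
    if (any(hi - lo > patchSize - 2))
        stop(sprintf("worm group (%.0f x %.0f px) does not fit a %d px patch",
                     hi[1] - lo[1], hi[2] - lo[2], patchSize), call. = FALSE)
    shift <- round(patchSize / 2 - (lo + hi) / 2)
    shapes <- lapply(shapes, transformShape, offset = shift)
    patch <- matrix(1, patchSize, patchSize)
    boxes <- vector("list", length(shapes))
    for (i in seq_along(shapes)) {
        r <- .rasterizeShape(shapes[[i]], patchSize, patchSize)
        patch[r$gx + 1L, r$gy + 1L] <-
            patch[r$gx + 1L, r$gy + 1L] * (1 - r$darkness)
        boxes[[i]] <- .maskBox(r$core, r$gx, r$gy)
    }
    unit <- do.call(rbind, boxes)
    unit$class <- 1L
    if (noiseSd > 0)
        patch <- pmax(patch + matrix(rnorm(length(patch), 0, noiseSd),
                                     nrow(patch)), 0)
    group <- .boxUnion(unit)
    group$class <- length(shapes)
    new("WormPatch", patch = patch, nWorms = length(shapes),
        unitBoxes = unit, groupBox = group)
}

.intersectionArea <- function(a, b) {
    iw <- min(a$x + a$w, b$x + b$w) - max(a$x, b$x)
    ih <- min(a$y + a$h, b$y + b$h) - max(a$y, b$y)
    max(0, iw) * max(0, ih)
}

#' Compose a Class-n model image of overlapping worms
#'
#' Samples n shapes from the library with replacement, applies a random
#' rotation (0-360 degrees) and zoom, and offsets them so that for n >= 2
#' every worm's box overlaps the union of the others (an overlap group).
#' Placements that do not fit the patch or do not overlap are resampled.
#'
#' @param library list of \linkS4class{WormShape}s.
#' @param n worms in the group (1..4); the patch's class label.
#' @param patchSize patch side length in pixels.
#' @param zoomRange random zoom range.
#' @param offsetSd standard deviation (pixels) of the random worm-to-worm
#'   offset; small values give heavily overlapped boxes.
#' @param noiseSd additive noise passed to \code{\link{renderModelImage}}.
#' @param maxRetries placement attempts before giving up.
#' @return a \linkS4class{WormPatch}.
#' @export
composeClassImage <- function(library, n, patchSize = 100,
                              zoomRange = c(0.8, 1.2), offsetSd = 6,
                              noiseSd = 0.02, maxRetries = 50L) {
    if (!is.list(library) || length(library) == 0L)
        stop("'library' must be a nonempty list of WormShape objects",
             call. = FALSE)
    n <- .assertCount(n, "n", 1L)
    if (n > 4L) stop("'n' must be in 1..4", call. = FALSE)
    for (attempt in seq_len(maxRetries)) {
        idx <- sample.int(length(library), n, replace = TRUE)
        placed <- list()
        ok <- TRUE
        for (i in seq_len(n)) {
            sh <- transformShape(library[[idx[i]]],
                                 rotation = runif(1, 0, 360),
                                 zoom = runif(1, zoomRange[1], zoomRange[2]))
            if (i == 1L) { placed[[1]] <- sh; next }
            done <- FALSE
            for (k in seq_len(20L)) {
                cand <- transformShape(sh, offset = rnorm(2, 0, offsetSd))
                bc <- .shapeBounds(cand)
                candBox <- data.frame(x = bc["xmin"], y = bc["ymin"],
                                      w = bc["xmax"] - bc["xmin"],
                                      h = bc["ymax"] - bc["ymin"])
                overlap <- any(vapply(placed, function(p) {
                    bp <- .shapeBounds(p)
                    .intersectionArea(candBox, data.frame(
                        x = bp["xmin"], y = bp["ymin"],
                        w = bp["xmax"] - bp["xmin"],
                        h = bp["ymax"] - bp["ymin"])) >= 1
                }, logical(1)))
                if (overlap) { placed[[i]] <- cand; done <- TRUE; break }
            }
            if (!done) { ok <- FALSE; break }
        }
        if (!ok) next
        patch <- tryCatch(renderModelImage(placed, patchSize, noiseSd),
                          error = function(e) NULL)
        if (is.null(patch)) next
        if (n >= 2L) {
            u <- patch@unitBoxes
            pair <- vapply(seq_len(n), function(i) max(vapply(
                setdiff(seq_len(n), i), function(j)
                    .intersectionArea(u[i, ], u[j, ]), numeric(1))),
                numeric(1))
            if (any(pair < 1)) next
        }
        return(patch)
    }
    stop(sprintf("could not compose a class-%d overlap group after %d tries",
                 n, maxRetries), call. = FALSE)
}

#' Generate a full simulated scene with two-granularity ground truth
#'
#' Draws N ~ uniform over \code{nModelsRange} worm groups with classes
#' sampled from \code{classMix}, composes each group and places the groups
#' at uniform-random, non-overlapping positions on the field. Ground truth
#' is emitted per worm (\code{unitBoxes}, all class 1) and per group
#' (\code{groupBoxes}, class = group size); worm count is conserved by
#' construction. With \code{pond = TRUE} the field gets a pond disk, rim and
#' illumination gradient (a raw-image lookalike for exercising the
#' pre-processing chain); otherwise the background is the flat 1.0 of a
#' corrected image.
#'
#' @param library list of \linkS4class{WormShape}s.
#' @param nModelsRange integer range of model images per field.
#' @param classMix sampling probabilities over classes 1..length(classMix)
#'   (must sum to 1).
#' @param fieldSize c(width, height) in pixels.
#' @param noiseSd scene-level additive Gaussian noise.
#' @param pond draw a pond disk and vignette.
#' @param seed optional seed recorded in the provenance.
#' @param patchSize,zoomRange,offsetSd passed to
#'   \code{\link{composeClassImage}}.
#' @param maxPlaceRetries placement attempts per group before the scene is
#'   declared saturated.
#' @return a \linkS4class{WormScene}.
#' @export
makeScene <- function(library, nModelsRange = c(10, 80),
                      classMix = rep(0.25, 4), fieldSize = c(704, 528),
                      noiseSd = 0.02, pond = FALSE, seed = NULL,
                      patchSize = 100, zoomRange = c(0.8, 1.2),
                      offsetSd = 6, maxPlaceRetries = 100L) {
    if (abs(sum(classMix) - 1) > 1e-8)
        stop("'classMix' must sum to 1", call. = FALSE)
    if (nModelsRange[1] > nModelsRange[2] || nModelsRange[1] < 1)
        stop("'nModelsRange' must be an increasing positive range",
             call. = FALSE)
    W <- .assertCount(fieldSize[1], "fieldSize[1]", 16L)
    H <- .assertCount(fieldSize[2], "fieldSize[2]", 16L)
    .withSeed(seed, {
        nChoices <- seq.int(nModelsRange[1], nModelsRange[2])
        N <- nChoices[sample.int(length(nChoices), 1L)]
        classes <- sample.int(length(classMix), N, replace = TRUE,
                              prob = classMix)
        pondGeom <- NULL
        if (pond) {
            pondGeom <- PondGeometry(
                centerX = W / 2 + runif(1, -10, 10),
                centerY = H / 2 + runif(1, -10, 10),
                radius = runif(1, 0.40, 0.46) * min(W, H))
            xs <- seq_len(W) - 1; ys <- seq_len(H) - 1
            dist <- sqrt(outer((xs - pondGeom@centerX)^2,
                               (ys - pondGeom@centerY)^2, "+"))
            ramp <- matrix(rep(0.9 + 0.2 * xs / (W - 1), H), W, H)
            base <- ifelse(dist <= pondGeom@radius, 0.82, 0.60)
            rim <- 1 - 0.5 * exp(-(dist - pondGeom@radius)^2 / (2 * 2^2))
            field <- base * ramp * rim
        } else {
            field <- matrix(1, W, H)
        }
        unitAll <- list(); groupAll <- list()
        placedGroups <- list()
        for (g in seq_len(N)) {
            patch <- composeClassImage(library, classes[g], patchSize,
                                       zoomRange, offsetSd, noiseSd = 0)
            gb <- patch@groupBox
            placedOk <- FALSE
            for (k in seq_len(maxPlaceRetries)) {
                offX <- floor(runif(1, 0, W - gb$w))
                offY <- floor(runif(1, 0, H - gb$h))
                cand <- data.frame(x = offX, y = offY,
                                   w = gb$w, h = gb$h)
                if (pond) {
                    corners <- cbind(c(cand$x, cand$x + cand$w,
                                       cand$x, cand$x + cand$w),
                                     c(cand$y, cand$y,
                                       cand$y + cand$h, cand$y + cand$h))
                    inside <- sqrt((corners[, 1] - pondGeom@centerX)^2 +
                                   (corners[, 2] - pondGeom@centerY)^2) <=
                              pondGeom@radius - 6
                    if (!all(inside)) next
                }
                pad <- data.frame(x = cand$x - 2, y = cand$y - 2,
                                  w = cand$w + 4, h = cand$h + 4)
                clash <- any(vapply(placedGroups, function(p)
                    .intersectionArea(pad, p) > 0, logical(1)))
                if (!clash) { placedOk <- TRUE; break }
            }
            if (!placedOk)
                stop(sprintf(paste0("scene placement saturated after group ",
                                    "%d of %d; reduce 'nModelsRange'"),
                             g, N), call. = FALSE)
            ## paste the patch region covered by the group box
            sx <- (gb$x + 1L):(gb$x + gb$w)      # patch cols (1-based)
            sy <- (gb$y + 1L):(gb$y + gb$h)
            fx <- (offX + 1L):(offX + gb$w)
            fy <- (offY + 1L):(offY + gb$h)
            field[fx, fy] <- field[fx, fy] * patch@patch[sx, sy]
            u <- patch@unitBoxes
            u$x <- u$x - gb$x + offX; u$y <- u$y - gb$y + offY
            u$group <- g
            unitAll[[g]] <- u
            groupAll[[g]] <- data.frame(x = offX, y = offY,
                                        w = gb$w, h = gb$h,
                                        class = patch@groupBox$class)
            placedGroups[[g]] <- data.frame(x = offX, y = offY,
                                            w = gb$w, h = gb$h)
        }
        if (noiseSd > 0)
            field <- pmax(field + matrix(rnorm(length(field), 0, noiseSd),
                                         W, H), 0)
        if (pond) field <- pmin(field, 1)
        new("WormScene", image = field,
            unitBoxes = do.call(rbind, unitAll),
            groupBoxes = do.call(rbind, groupAll),
            pond = pondGeom,
            provenance = list(seed = seed, nModelsRange = nModelsRange,
                              classMix = classMix, fieldSize = c(W, H),
                              noiseSd = noiseSd, pond = pond,
                              patchSize = patchSize, zoomRange = zoomRange,
                              offsetSd = offsetSd))
    })
}

#' Write a scene dataset with annotations in both conventions
#'
#' Writes each scene as an 8-bit PNG plus Darknet TXT annotations in the
#' one-class convention (\code{labels_occ/}: every worm a class-1 unit box)
#' and the multi-class convention (\code{labels_mcc/}: group boxes with
#' class labels), JSON annotations at both granularities (\code{json/}) and
#' a manifest listing files, seeds and counts. Rerunning with the same seed
#' reproduces the dataset byte for byte.
#'
#' @param outDir output directory (created if needed).
#' @param nTrain,nVal scenes in the train and val splits (0 allowed).
#' @param library list of \linkS4class{WormShape}s; drawn internally from
#'   \code{shapeParams} when NULL.
#' @param seed base seed; per-scene seeds are derived from it.
#' @param libSize library size when \code{library} is NULL.
#' @param shapeParams a \code{\link{wormShapeParams}}.
#' @param sceneArgs list of extra arguments for \code{\link{makeScene}}.
#' @return the manifest, invisibly (also written as \code{manifest.json}).
#' @export
makeDataset <- function(outDir, nTrain, nVal, library = NULL, seed = 1,
                        libSize = 30, shapeParams = wormShapeParams(),
                        sceneArgs = list()) {
    nTrain <- .assertCount(nTrain, "nTrain", 0L)
    nVal <- .assertCount(nVal, "nVal", 0L)
    seed <- .assertCount(seed, "seed", 0L)
    for (d in c("images", "labels_occ", "labels_mcc", "json"))
        dir.create(file.path(outDir, d), recursive = TRUE,
                   showWarnings = FALSE)
    if (is.null(library))
        library <- makeShapeLibrary(libSize, shapeParams, seed = seed)
    splits <- rep(c("train", "val"), c(nTrain, nVal))
    entries <- vector("list", length(splits))
    for (i in seq_along(splits)) {
        sceneSeed <- (seed + 7919L * i) %% .Machine$integer.max
        sc <- do.call(makeScene, c(list(library = library, seed = sceneSeed),
                                   sceneArgs))
        stem <- sprintf("%s_%04d", splits[i], i)
        img <- file.path("images", paste0(stem, ".png"))
        W <- nrow(sc@image); H <- ncol(sc@image)
        EBImage::writeImage(EBImage::Image(pmin(pmax(sc@image, 0), 1)),
                            file.path(outDir, img))
        occ <- file.path("labels_occ", paste0(stem, ".txt"))
        mcc <- file.path("labels_mcc", paste0(stem, ".txt"))
        writeDarknetBoxes(sc@unitBoxes, file.path(outDir, occ), W, H)
        writeDarknetBoxes(sc@groupBoxes, file.path(outDir, mcc), W, H)
        ju <- file.path("json", paste0(stem, "_unit.json"))
        jg <- file.path("json", paste0(stem, "_group.json"))
        writeBoxesJSON(sc@unitBoxes, file.path(outDir, ju),
                       paste0(stem, ".png"), W, H, "unit")
        writeBoxesJSON(sc@groupBoxes, file.path(outDir, jg),
                       paste0(stem, ".png"), W, H, "group")
        entries[[i]] <- list(id = stem, split = splits[i], seed = sceneSeed,
                             image = img, nWorms = nrow(sc@unitBoxes),
                             nGroups = nrow(sc@groupBoxes),
                             annotations = list(occ = occ, mcc = mcc,
                                                unitJSON = ju,
                                                groupJSON = jg))
    }
    manifest <- list(seed = seed, nTrain = nTrain, nVal = nVal,
                     libSize = length(library), sceneArgs = sceneArgs,
                     scenes = entries)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
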