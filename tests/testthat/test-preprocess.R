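test_that("resizeAndGray resizes, converts luminance, and validates", {
    # identity resize keeps pixel values
    set.seed(2)
    m <- matrix(runif(80 * 60), 80, 60)
    expect_equal(resizeAndGray(m, 80, 60), m)
    # constant RGB maps to a constant gray of the same value
    rgb <- array(0.4, c(64, 48, 3))
    out <- resizeAndGray(rgb, 32, 24)
    expect_equal(dim(out), c(32L, 24L))
    expect_equal(max(abs(out - 0.4)), 0, tolerance = 1e-6)
    # large frame down to the working resolution
    big <- matrix(runif(512 * 384), 512, 384)
    expect_equal(dim(resizeAndGray(big, 128, 96)), c(128L, 96L))
    expect_error(resizeAndGray(m, 0, 10), "targetWidth")
    expect_error(resizeAndGray("no/such/file.png", 10, 10), "cannot read")
})

test_that("background estimation removes worm-scale dark strokes", {
    # constant image: closing and median are identities
    flat <- matrix(0.8, 120, 90)
    expect_equal(estimateBackground(flat, 25, 3), flat)
    # a 5-px-wide dark stroke vanishes under a 25-px disc
    img <- matrix(0.8, 120, 90)
    img[40:100, 44:48] <- 0.3
    b <- estimateBackground(img, 25, 3)
    expect_lt(max(abs(b - 0.8)), 2 / 255)
    expect_error(estimateBackground(img, 121, 3), "exceeds")
    expect_error(estimateBackground(img, 24, 3), "odd")
})

test_that("grayscale closing is extensive and idempotent", {
    set.seed(31)
    for (i in 1:5) {
        a <- matrix(runif(60 * 50), 60, 50)
        b1 <- estimateBackground(a, 9, 1)   # median disabled
        expect_true(all(b1 >= a - 1e-12))
        expect_equal(estimateBackground(b1, 9, 1), b1, tolerance = 1e-12)
    }
})

test_that("DoG is zero on constants, zero-sum on periodic input, and traces a step edge", {
    expect_equal(dogEdge(matrix(0.7, 50, 50)), matrix(0, 50, 50))
    set.seed(4)
    r <- matrix(runif(64 * 64), 64, 64)
    expect_equal(sum(dogEdge(r)), 0, tolerance = 1e-8)
    # vertical step at x = 99.5 (0-based); compare to the analytic
    # difference of Gaussian CDFs and check the zero crossing and extrema
    step <- matrix(0, 200, 40); step[101:200, ] <- 1
    d <- dogEdge(step, 20, 30)
    prof <- d[, 20]
    x <- 0:199
    analytic <- pnorm((x - 99.5) / (19 / 6)) - pnorm((x - 99.5) / (29 / 6))
    expect_lt(max(abs(prof[30:170] - analytic[30:170])), 0.02)
    expect_lt(prof[100], 0); expect_gt(prof[101], 0)  # sign flip at edge
    # extrema flank the edge (window excludes the wrap-around step)
    win <- 50:150
    expect_lt(abs(win[which.max(prof[win])] - 1 - 99.5), 8)
    expect_lt(abs(win[which.min(prof[win])] - 1 - 99.5), 8)
    expect_equal(dogEdge(step, 20, 30, largeMinusSmall = TRUE), -d)
    expect_error(dogEdge(step, 30, 30), "smaller")
})

test_that("circle Hough recovers a synthetic pond rim within 2 px", {
    img <- ringImage(704, 528, 352, 264, 200)
    pond <- findPondEdge(img, 150, 260)
    expect_lt(abs(pond@centerX - 352), 2)
    expect_lt(abs(pond@centerY - 264), 2)
    expect_lt(abs(pond@radius - 200), 2)
})

test_that("radius range restriction picks the in-range ring", {
    img <- ringImage(500, 500, 250, 250, 100) +
           ringImage(500, 500, 250, 250, 200)
    pond <- findPondEdge(img, 150, 250)
    expect_lt(abs(pond@radius - 200), 2)
    pondSmall <- findPondEdge(img, 50, 150)
    expect_lt(abs(pondSmall@radius - 100), 2)
})

test_that("pond search fails loudly on edgeless images", {
    expect_error(findPondEdge(matrix(0, 200, 200), 20, 100), "pond not found")
    set.seed(9)
    noise <- matrix(runif(200 * 200, 0, 0.01), 200, 200)
    expect_error(findPondEdge(noise, 20, 100), "pond not found")
})

test_that("background correction divides, fills outside, and leaves the pond untouched", {
    pond <- PondGeometry(60, 45, 30)
    a <- matrix(0.8, 120, 90)
    # self-division is identically 1
    expect_equal(backgroundCorrect(a, a, pond), matrix(1, 120, 90))
    # worms over background 0.8: inside-pond background within 1% of 1.0
    img <- a; img[50:70, 40:44] <- 0.3
    b <- estimateBackground(img, 25, 3)
    d <- backgroundCorrect(img, b, pond)
    xs <- 0:119; ys <- 0:89
    dist2 <- outer((xs - 60)^2, (ys - 45)^2, "+")
    inside <- dist2 <= 30^2
    bgInside <- inside & img > 0.5
    expect_lt(max(abs(d[bgInside] - 1)), 0.01)
    # inside pixels are bit-identical to a / b
    raw <- img / pmax(b, 1 / 255)
    expect_identical(d[inside], raw[inside])
    # every outside pixel equals the periphery mean
    expect_equal(length(unique(d[!inside])), 1L)
    expect_error(backgroundCorrect(a, a[1:50, ], pond), "identical dimensions")
})

test_that("the full pipeline flattens a vignetted pond scene and is deterministic", {
    lib <- testLibrary()
    sc <- makeScene(lib, nModelsRange = c(8, 10), pond = TRUE, seed = 11,
                    noiseSd = 0.01)
    cfg <- preprocessConfig(radiusRange = c(150, 260))
    out1 <- preprocessPipeline(sceneImage(sc), cfg, keepStages = TRUE)
    out2 <- preprocessPipeline(sceneImage(sc), cfg)
    expect_identical(out1$image, out2$image)   # no randomness
    truePond <- pondGeometry(sc)
    expect_lt(abs(out1$pond@centerX - truePond@centerX), 3)
    expect_lt(abs(out1$pond@radius - truePond@radius), 3)
    # the raw scene has a left-right illumination ramp; division flattens it
    xs <- 0:(nrow(out1$image) - 1); ys <- 0:(ncol(out1$image) - 1)
    dist2 <- outer((xs - truePond@centerX)^2, (ys - truePond@centerY)^2, "+")
    inside <- dist2 < (truePond@radius - 12)^2
    bg <- inside & sceneImage(sc) > 0.55      # exclude worm pixels
    raw <- sceneImage(sc)
    rampSpread <- diff(quantile(raw[bg], c(0.05, 0.95)))
    flatSpread <- diff(quantile(out1$image[bg], c(0.05, 0.95)))
    expect_lt(flatSpread, rampSpread / 2)
    expect_named(out1$stages, c("A", "B", "C"))
})

test_that("pipeline errors carry the failing stage name", {
    err <- tryCatch(preprocessPipeline(matrix(0.5, 300, 300)),
                    error = conditionMessage)
    expect_match(err, "find_pond_edge")
})

test_that("corrected images write to PNG with an exact float sidecar", {
    set.seed(6)
    d <- matrix(runif(60 * 40, 0, 1.5), 60, 40)
    f <- withr::local_tempfile(fileext = ".png")
    writeCorrectedImage(d, f, keepFloat = TRUE)
    expect_true(file.exists(f))
    expect_identical(readNpy(paste0(f, ".npy")), d)
    png <- resizeAndGray(f, 60, 40)
    expect_lt(max(abs(png - pmin(d, 2) / 2)), 1 / 255)
})
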