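test_that("worm shapes are reproducible, bounded in length, and continuous", {
    params <- wormShapeParams()
    set.seed(42); s1 <- makeWormShape(params)
    set.seed(42); s2 <- makeWormShape(params)
    expect_identical(s1@skeleton, s2@skeleton)
    set.seed(17)
    for (i in 1:200) {
        s <- makeWormShape(params)
        len <- sum(sqrt(rowSums(diff(s@skeleton)^2)))
        expect_gte(len, params$lengthRange[1] * 0.95)
        expect_lte(len, params$lengthRange[2] * 1.05)
        expect_true(all(sqrt(rowSums(diff(s@skeleton)^2)) < 5))
        expect_true(all(s@halfWidth > 0))
    }
})

test_that("coil postures self-intersect; straight strokes do not", {
    params <- wormShapeParams(postureWeights = c(wave = 0, omega = 0,
                                                 coil = 1))
    set.seed(33)
    for (i in 1:40)
        expect_true(shapeSelfIntersects(makeWormShape(params)))
    expect_false(shapeSelfIntersects(straightWorm()))
})

test_that("rendering a known straight worm gives the expected tight box", {
    patch <- renderModelImage(list(straightWorm(60, 2)), 100, noiseSd = 0)
    u <- unitBoxes(patch)
    expect_equal(nrow(u), 1L)
    expect_lte(abs(u$w - 60), 2)
    expect_lte(abs(u$h - 4), 2)
    # group box of a single worm is the unit box
    expect_equal(as.numeric(u[1, c("x", "y", "w", "h")]),
                 as.numeric(groupBoxes(patch)[1, c("x", "y", "w", "h")]))
    # worm is darker than the background
    img <- sceneImage(patch)
    expect_lt(min(img), 0.6)
    expect_equal(max(img), 1)
})

test_that("model images carry one unit box per worm and a minimal group box", {
    lib <- testLibrary()
    set.seed(8)
    patch <- composeClassImage(lib, 4)
    expect_equal(nWorms(patch), 4L)
    expect_equal(nrow(unitBoxes(patch)), 4L)
    expect_equal(groupBoxes(patch)$class, 4L)
    u <- unitBoxes(patch); g <- groupBoxes(patch)
    # minimality: each side of the group box touches some unit box
    expect_equal(min(u$x), g$x)
    expect_equal(min(u$y), g$y)
    expect_equal(max(u$x + u$w), g$x + g$w)
    expect_equal(max(u$y + u$h), g$y + g$h)
    expect_error(renderModelImage(list()), "nonempty")
})

test_that("overlap groups overlap: every unit box meets another", {
    lib <- testLibrary()
    set.seed(12)
    for (n in 2:4) {
        u <- unitBoxes(composeClassImage(lib, n))
        for (i in seq_len(n)) {
            inter <- vapply(setdiff(seq_len(n), i), function(j) {
                iw <- min(u$x[i] + u$w[i], u$x[j] + u$w[j]) -
                      max(u$x[i], u$x[j])
                ih <- min(u$y[i] + u$h[i], u$y[j] + u$h[j]) -
                      max(u$y[i], u$y[j])
                max(0, iw) * max(0, ih)
            }, numeric(1))
            expect_gte(max(inter), 1)
        }
    }
    set.seed(5); p1 <- composeClassImage(lib, 3)
    set.seed(5); p2 <- composeClassImage(lib, 3)
    expect_identical(sceneImage(p1), sceneImage(p2))
})

test_that("scenes conserve worm counts and keep ground truth in frame", {
    lib <- testLibrary()
    for (seed in c(1, 2, 3)) {
        sc <- makeScene(lib, nModelsRange = c(8, 14), seed = seed)
        u <- unitBoxes(sc); g <- groupBoxes(sc)
        expect_equal(sum(g$class), nrow(u))
        W <- nrow(sceneImage(sc)); H <- ncol(sceneImage(sc))
        expect_true(all(u$x >= 0 & u$y >= 0 &
                        u$x + u$w <= W & u$y + u$h <= H))
        expect_true(all(g$x >= 0 & g$y >= 0 &
                        g$x + g$w <= W & g$y + g$h <= H))
        # every unit box sits inside its group box
        for (i in seq_len(nrow(u))) {
            gb <- g[u$group[i], ]
            expect_gte(u$x[i], gb$x); expect_gte(u$y[i], gb$y)
            expect_lte(u$x[i] + u$w[i], gb$x + gb$w)
            expect_lte(u$y[i] + u$h[i], gb$y + gb$h)
        }
    }
})

test_that("scene generation is deterministic under a fixed seed", {
    lib <- testLibrary()
    sc1 <- makeScene(lib, nModelsRange = c(6, 9), seed = 42)
    sc2 <- makeScene(lib, nModelsRange = c(6, 9), seed = 42)
    expect_identical(sceneImage(sc1), sceneImage(sc2))
    expect_identical(unitBoxes(sc1), unitBoxes(sc2))
    expect_identical(groupBoxes(sc1), groupBoxes(sc2))
})

test_that("a degenerate class mix yields exactly N singleton groups", {
    lib <- testLibrary()
    sc <- makeScene(lib, nModelsRange = c(10, 10),
                    classMix = c(1, 0, 0, 0), seed = 2)
    expect_equal(nrow(groupBoxes(sc)), 10L)
    expect_equal(nrow(unitBoxes(sc)), 10L)
    expect_true(all(groupBoxes(sc)$class == 1L))
})

test_that("connected components recover the worm count on spaced singletons", {
    # strongly stained worms and no noise, so a plain threshold suffices
    lib <- makeShapeLibrary(12, wormShapeParams(intensityRange = c(0.5, 0.6)),
                            seed = 123)
    for (seed in c(2, 6)) {
        sc <- makeScene(lib, nModelsRange = c(12, 12),
                        classMix = c(1, 0, 0, 0), noiseSd = 0, seed = seed)
        labels <- EBImage::bwlabel(sceneImage(sc) < 0.9)
        expect_equal(max(labels), nWorms(sc))
    }
})

test_that("datasets write both annotation conventions plus a stable manifest", {
    lib <- testLibrary()
    out1 <- withr::local_tempdir()
    man1 <- makeDataset(out1, nTrain = 4, nVal = 2, library = lib, seed = 9,
                        sceneArgs = list(nModelsRange = c(5, 7)))
    expect_length(list.files(file.path(out1, "images")), 6L)
    txt <- c(list.files(file.path(out1, "labels_occ")),
             list.files(file.path(out1, "labels_mcc")))
    expect_length(txt, 12L)   # two conventions per image
    # annotations round-trip against the manifest's worm counts
    for (e in man1$scenes) {
        W <- 704; H <- 528
        occ <- readDarknetBoxes(file.path(out1, e$annotations$occ), W, H)
        mcc <- readDarknetBoxes(file.path(out1, e$annotations$mcc), W, H)
        expect_equal(nrow(occ), e$nWorms)
        expect_equal(sum(mcc$class), e$nWorms)
        ju <- readBoxesJSON(file.path(out1, e$annotations$unitJSON))
        expect_identical(ju$granularity, "unit")
        expect_equal(nrow(ju$boxes), e$nWorms)
    }
    # rerun with the same seed: byte-identical manifest
    out2 <- withr::local_tempdir()
    makeDataset(out2, nTrain = 4, nVal = 2, library = lib, seed = 9,
                sceneArgs = list(nModelsRange = c(5, 7)))
    expect_identical(readLines(file.path(out1, "manifest.json")),
                     readLines(file.path(out2, "manifest.json")))
    # empty training split is valid
    out3 <- withr::local_tempdir()
    man3 <- makeDataset(out3, nTrain = 0, nVal = 1, library = lib, seed = 1,
                        sceneArgs = list(nModelsRange = c(4, 5)))
    expect_equal(man3$nTrain, 0L)
    expect_length(list.files(file.path(out3, "images")), 1L)
})
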