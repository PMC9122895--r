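test_that("class division conserves worm counts", {
    d3 <- wormBoxes(0, 0, 10, 10, class = 3L, confidence = 0.8)
    out <- divideClasses(d3)
    expect_equal(nrow(out), 3L)
    expect_true(all(out$class == 1L))
    expect_true(all(out$confidence == 0.8))
    d1 <- wormBoxes(5, 5, 8, 8, class = 1L)
    expect_equal(divideClasses(d1), d1)
    mix <- wormBoxes(x = c(0, 20), y = 0, w = 10, h = 10, class = c(2L, 1L))
    expect_equal(nrow(divideClasses(mix)), 3L)
    set.seed(3)
    for (i in 1:20) {
        n <- sample(1:10, 1)
        dets <- wormBoxes(x = runif(n, 0, 100), y = runif(n, 0, 100),
                          w = 10, h = 10, class = sample(1:4, n, TRUE))
        expect_equal(nrow(divideClasses(dets)), sum(dets$class))
    }
})

test_that("matching credits worms per the division-based counting rules", {
    unit <- wormBoxes(x = c(10, 40, 70), y = 10, w = 20, h = 15, class = 1L)
    unit$group <- 1:3
    group <- unit; group$group <- NULL
    gt <- list(unit = unit, group = group)
    # perfect one-class detections
    dets <- unit; dets$group <- NULL; dets$confidence <- 0.9
    cc <- matchAndCount(dets, gt, "occ")
    expect_equal(unclass(cc)[c("tp", "fp", "fn")],
                 list(tp = 3, fp = 0, fn = 0))
    # a detection at IoU below threshold scores 0 TP, 1 FP, 1 FN
    off <- wormBoxes(22, 10, 20, 15, class = 1L, confidence = 0.9)
    expect_lt(boxIoU(off, unit[1, ]), 0.5)
    cc1 <- matchAndCount(off, list(unit = unit[1, ], group = group[1, ]),
                         "occ")
    expect_equal(unclass(cc1)[c("tp", "fp", "fn")],
                 list(tp = 0, fp = 1, fn = 1))
})

test_that("a class-2 detection of a 3-worm group counts 2 found and 1 missed", {
    unit <- wormBoxes(x = c(10, 12, 14), y = 10, w = 20, h = 15, class = 1L)
    unit$group <- 1L
    group <- wormBoxes(10, 10, 24, 15, class = 3L)
    det <- wormBoxes(10, 10, 24, 15, class = 2L, confidence = 0.9)
    cc <- matchAndCount(det, list(unit = unit, group = group), "mcc")
    expect_equal(unclass(cc)[c("tp", "fp", "fn")],
                 list(tp = 2, fp = 0, fn = 1))
    # overclaiming flips to false positives
    det4 <- det; det4$class <- 4L
    cc4 <- matchAndCount(det4, list(unit = unit, group = group), "mcc")
    expect_equal(unclass(cc4)[c("tp", "fp", "fn")],
                 list(tp = 3, fp = 1, fn = 0))
    # unmatched detections and groups contribute their full class counts
    lone <- wormBoxes(150, 100, 20, 15, class = 2L, confidence = 0.8)
    cc0 <- matchAndCount(lone, list(unit = unit, group = group), "mcc")
    expect_equal(unclass(cc0)[c("tp", "fp", "fn")],
                 list(tp = 0, fp = 2, fn = 3))
    # inconsistent ground truth is rejected
    badGroup <- group; badGroup$class <- 5L
    expect_error(matchAndCount(det, list(unit = unit, group = badGroup),
                               "mcc"), "inconsistent")
})

test_that("precision, recall and F1 reproduce the reported operating points", {
    expect_equal(detectionPrecision(evalCounts(tp = 91, fp = 9)), 0.91)
    expect_equal(detectionRecall(evalCounts(tp = 93, fn = 7)), 0.93)
    expect_equal(detectionRecall(evalCounts(tp = 79, fn = 21)), 0.79)
    expect_equal(round(f1Score(0.91, 0.79), 2), 0.85)
    expect_equal(round(f1Score(0.91, 0.93), 2), 0.92)
    # conventions at empty denominators
    expect_equal(detectionPrecision(evalCounts()), 1)
    expect_equal(detectionRecall(evalCounts()), 1)
    expect_equal(detectionPrecision(evalCounts(fp = 5)), 0)
    expect_equal(f1Score(0, 0), 0)
    # harmonic mean of equals
    for (x in c(0.2, 0.5, 0.91)) expect_equal(f1Score(x, x), x)
})

test_that("PR curves match an exhaustive hand-enumerated sweep", {
    gt <- list(unit = {
        u <- wormBoxes(x = c(0, 50, 100), y = 0, w = 20, h = 20, class = 1L)
        u$group <- 1:3; u
    }, group = wormBoxes(x = c(0, 50, 100), y = 0, w = 20, h = 20,
                         class = 1L))
    # 3 TPs at conf .9/.7/.5 interleaved with 2 FPs at .8/.6
    dets <- wormBoxes(x = c(0, 200, 50, 240, 100), y = 0, w = 20, h = 20,
                      class = 1L,
                      confidence = c(0.9, 0.8, 0.7, 0.6, 0.5))
    curve <- prCurve(dets, gt, "occ")
    expect_equal(curve$cutoff, c(0.9, 0.8, 0.7, 0.6, 0.5))
    expect_equal(curve$recall, c(1, 1, 2, 2, 3) / 3)
    expect_equal(curve$precision, c(1 / 1, 1 / 2, 2 / 3, 2 / 4, 3 / 5))
    # AP by direct step-sum: (1/3)(1) + 0 + (1/3)(2/3) + 0 + (1/3)(3/5)
    expect_equal(averagePrecision(curve), 1 / 3 + 2 / 9 + 1 / 5)
    # detection order does not matter
    shuf <- dets[c(4, 1, 5, 2, 3), ]
    expect_equal(prCurve(shuf, gt, "occ"), curve)
})

test_that("recall is non-decreasing along every PR sweep", {
    set.seed(19)
    for (i in 1:25) {
        dets <- randomToyInstance()
        gt <- list(unit = dets[seq_len(min(3, nrow(dets))),
                               c("x", "y", "w", "h", "class")],
                   group = dets[seq_len(min(3, nrow(dets))),
                                c("x", "y", "w", "h", "class")])
        curve <- prCurve(dets, gt, "occ")
        expect_true(all(diff(curve$recall) >= -1e-12))
        expect_true(all(curve$recall >= 0 & curve$recall <= 1))
        expect_true(all(curve$precision >= 0 & curve$precision <= 1))
    }
    expect_error(prCurve(wormBoxes(0, 0, 2, 2, confidence = 0.5),
                         list(unit = wormBoxes(numeric(0), numeric(0),
                                               numeric(0), numeric(0)),
                              group = wormBoxes(numeric(0), numeric(0),
                                                numeric(0), numeric(0))),
                         "occ"),
                 "no ground-truth")
})

test_that("average precision handles boundary curves", {
    expect_equal(averagePrecision(data.frame(recall = 1, precision = 1)), 1)
    expect_equal(averagePrecision(data.frame(recall = numeric(0),
                                             precision = numeric(0))), 0)
    expect_equal(averagePrecision(data.frame(recall = c(0.5, 1),
                                             precision = c(1, 0.5))), 0.75)
})

test_that("detection errors and their summaries follow the worked examples", {
    expect_identical(detectionError(38, 46), -8L)
    expect_identical(detectionError(50, 46), 4L)
    expect_identical(detectionError(46, 46), 0L)
    s0 <- summarizeErrors(c(0, 0, 0))
    expect_equal(s0$mean, 0); expect_equal(s0$sd, 0)
    s <- summarizeErrors(c(-2, 2))
    expect_equal(s$mean, 0)
    expect_equal(round(s$sd, 2), 2.83)   # sample (n-1) form
    expect_equal(sum(s$histogram$count), 2L)
    set.seed(40)
    e <- sample(-6:4, 30, TRUE)
    expect_equal(sum(summarizeErrors(e)$histogram$count), 30L)
    expect_error(summarizeErrors(integer(0)), "nonempty")
})

test_that("the class-design arithmetic reproduces the pond capacity estimate", {
    d <- classDesign()
    expect_equal(d$pondArea, 19.625)
    expect_equal(d$movementArea, 0.49)
    expect_equal(d$capacity, 40)
    expect_equal(d$overlapEstimate, 3)
})

test_that("full evaluations conserve worms and keep metrics in range", {
    lib <- testLibrary()
    sc <- makeScene(lib, nModelsRange = c(8, 10), seed = 15)
    for (mode in c("occ", "mcc")) {
        dets <- simulateDetector(sc, mode, seed = 44)
        cc <- matchAndCount(dets, sc, mode)
        expect_equal(cc$tp + cc$fn, nWorms(sc))
        p <- detectionPrecision(cc); r <- detectionRecall(cc)
        f <- f1Score(p, r)
        expect_true(all(c(p, r, f) >= 0 & c(p, r, f) <= 1))
        expect_lte(f, max(p, r) + 1e-12)
        ap <- averagePrecision(prCurve(dets, sc, mode))
        expect_gte(ap, 0); expect_lte(ap, 1)
    }
})
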