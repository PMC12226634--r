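# Overlap/contour/temporal-consistency metrics and detection evaluation,
# checked against brute-force enumeration oracles.

test_that("mask warping follows the stated rounding and vacancy rules", {
  m <- matrix(0L, 6, 6)
  m[2:4, 2:4] <- 2L
  zero <- array(0, c(6, 6, 2))
  expect_identical(warpMask(m, zero), m)
  # uniform (0, +1) integer flow: shift one column right, vacated background
  fl <- zero; fl[, , 2] <- 1
  want <- matrix(0L, 6, 6); want[2:4, 3:5] <- 2L
  expect_identical(warpMask(m, fl), want)
  # sub-half flow rounds to zero
  fl04 <- zero; fl04[, , 2] <- 0.4
  expect_identical(warpMask(m, fl04), m)
  # half rounds away from zero
  fl05 <- zero; fl05[, , 2] <- 0.5
  expect_identical(warpMask(m, fl05), want)
  fln <- zero; fln[, , 2] <- -0.5
  wantL <- matrix(0L, 6, 6); wantL[2:4, 1:3] <- 2L
  expect_identical(warpMask(m, fln), wantL)
  expect_error(warpMask(m, array(0, c(5, 6, 2))), "flow shape")
})

test_that("integer flow preserves the foreground label multiset of in-frame pixels", {
  set.seed(9)
  for (rep in 1:20) {
    m <- randomMask(8, 8, 3)
    fl <- array(0, c(8, 8, 2))
    dr <- sample(-2:2, 1); dc <- sample(-2:2, 1)
    fl[, , 1] <- dr; fl[, , 2] <- dc
    w <- warpMask(m, fl)
    rIn <- pmax(1, 1 - dr):pmin(8, 8 - dr)
    cIn <- pmax(1, 1 - dc):pmin(8, 8 - dc)
    expect_identical(table(w[w > 0]),
                     table(m[rIn, cIn][m[rIn, cIn] > 0]))
  }
})

test_that("macro overlap agrees with brute-force pixel enumeration", {
  # worked example: two 8-pixel class-1 regions overlapping in 4 pixels
  a <- matrix(0L, 6, 6); a[2:3, 2:5] <- 1L
  b <- matrix(0L, 6, 6); b[3:4, 2:5] <- 1L       # shifted one row down
  ov <- macroOverlap(a, b)
  cls1 <- ov$perClass[ov$perClass$class_id == 1L, ]
  expect_equal(cls1$dice, 0.5)
  expect_equal(cls1$iou, 1 / 3)
  bg <- bfOverlap(a, b, 0L)
  expect_equal(ov$dice, mean(c(bg["dice"], 0.5)), ignore_attr = TRUE)

  set.seed(123)
  for (rep in 1:100) {
    x <- randomMask(); y <- randomMask()
    got <- macroOverlap(x, y)
    want <- bfMacroOverlap(x, y)
    expect_lt(abs(got$dice - want["dice"]), 1e-12)
    expect_lt(abs(got$iou - want["iou"]), 1e-12)
    # symmetry
    rev <- macroOverlap(y, x)
    expect_identical(got$dice, rev$dice)
    expect_identical(got$iou, rev$iou)
  }
  expect_identical(macroOverlap(a, a)$dice, 1)
  expect_error(macroOverlap(a, matrix(0L, 5, 6)), "shape mismatch")
})

test_that("disjoint same-class regions score zero overlap", {
  a <- matrix(0L, 8, 8); a[2:3, 2:5] <- 1L
  b <- matrix(0L, 8, 8); b[6:7, 2:5] <- 1L
  ov <- macroOverlap(a, b)
  cls1 <- ov$perClass[ov$perClass$class_id == 1L, ]
  expect_identical(cls1$dice, 0)
  expect_identical(cls1$iou, 0)
})

test_that("contour distance matches hand-computable geometries", {
  expect_identical(contourDistance(matrix(c(0L, 1L, 1L, 0L), 2, 2),
                                   matrix(c(0L, 1L, 1L, 0L), 2, 2)), 0)
  # two 1-pixel-wide vertical lines 2 columns apart
  a <- matrix(0L, 8, 8); a[2:7, 3] <- 1L
  b <- matrix(0L, 8, 8); b[2:7, 5] <- 1L
  expect_equal(contourDistance(a, b), 2)
  # class present in exactly one mask on a 3x4 grid: diagonal penalty 5
  a2 <- matrix(0L, 3, 4); a2[2, 2] <- 1L
  b2 <- matrix(0L, 3, 4)
  expect_equal(contourDistance(a2, b2), 5)
  expect_true(is.na(suppressWarnings(contourDistance(b2, b2))))
  expect_true(attr(contourDistance(b2, b2), "no_contours"))
  # penalty can be disabled
  expect_true(is.na(contourDistance(a2, b2, flickerPenalty = FALSE)))
})

test_that("contour distance agrees with brute-force enumeration and is symmetric", {
  set.seed(77)
  for (rep in 1:100) {
    x <- randomMask(); y <- randomMask()
    got <- contourDistance(x, y)
    want <- bfContourDistance(x, y)
    if (is.na(want)) expect_true(is.na(got))
    else expect_lt(abs(got - want), 1e-12)
    expect_identical(got, contourDistance(y, x))
  }
})

test_that("the dense flow estimator is near-zero on identical frames", {
  b <- demoScene(T = 4)
  f <- getFrame(b@frames, 0)
  fl <- computeFlow(f, f, method = "estimated")
  expect_lt(stats::median(sqrt(fl[, , 1]^2 + fl[, , 2]^2)), 0.1)
  expect_error(computeFlow(f, f[1:10, , ], method = "estimated"),
               "shape mismatch")
  expect_error(computeFlow(f, f, method = "ground_truth"),
               "no ground-truth flow available")
})

test_that("the ground-truth flow provider returns the configured velocities", {
  b <- demoScene(T = 6, entry = 0, exit = 6, velocity = c(1, 1))
  fl <- computeFlow(getFrame(b@frames, 0), getFrame(b@frames, 1),
                    method = "ground_truth", gtFlow = b@flow[[1]])
  obj <- getMask(b@masks, 0) == 3L
  expect_true(all(fl[, , 1][obj] == 1))
  expect_true(all(fl[, , 2][obj] == 1))
  expect_true(all(fl[, , 1][getMask(b@masks, 0) == 0L] == 0))
})

test_that("ground-truth masks with exact flow score perfect warped overlap", {
  b <- demoScene(T = 20, entry = 5, exit = 15)
  rep <- temporalConsistencyReport(b@frames, b@masks, "ground_truth",
                                   b@flow)
  # pairs without an entry/exit are exactly 1; entry pair (4,5) and exit
  # pair (14,15) are penalised
  eventPairs <- c(4, 14)
  for (t in setdiff(0:18, eventPairs)) {
    expect_identical(rep@perPair$dice_of[t + 1], 1)
    expect_identical(rep@perPair$iou_of[t + 1], 1)
  }
  expect_lt(rep@perPair$dice_of[5], 1)
  expect_error(temporalConsistencyReport(b@frames,
                 MaskSequence(b@masks@masks[1:5]), "ground_truth", b@flow),
               "length mismatch")
})

test_that("static scenes score zero contour distance and unit inter-frame IoU", {
  b <- demoScene(T = 8, entry = 0, exit = 8, velocity = c(0, 0))
  rep <- temporalConsistencyReport(b@frames, b@masks, "ground_truth",
                                   b@flow)
  expect_identical(unname(rep@means["cd_t"]), 0)
  expect_identical(unname(rep@means["iou_t"]), 1)
})

test_that("flickering masks score worse than stable ones on both CD_T and IoU_T", {
  b <- demoScene(T = 10, entry = 0, exit = 10, velocity = c(0, 0))
  flicker <- b@masks@masks
  for (t in seq(2, 10, by = 2)) {
    m <- flicker[[t]]
    m[m == 3L] <- 0L        # drop the rectangle on odd frames
    flicker[[t]] <- m
  }
  stable <- temporalConsistencyReport(b@frames, b@masks, "ground_truth",
                                      b@flow)
  flick <- temporalConsistencyReport(b@frames, MaskSequence(flicker),
                                     "ground_truth", b@flow)
  expect_lt(flick@means["iou_t"], stable@means["iou_t"])
  expect_gt(flick@means["cd_t"], stable@means["cd_t"])
})

test_that("greedy matching resolves classes, thresholds and score order", {
  H <- 8; W <- 8
  mk <- function(classes, scores, boxes)
    DetectionSet(0L, classes, scores, boxes,
                 replicate(length(classes), matrix(1, H, W),
                           simplify = FALSE), dims = c(H, W))
  gt <- mk(2L, 1, rbind(c(0, 0, 0.5, 0.5)))
  # one pred with IoU 0.6 >= 0.5 and matching class
  pred <- mk(2L, 0.9, rbind(c(0, 0, 0.5, 0.35)))
  expect_equal(boxIoU(pred@boxes[1, ], gt@boxes[1, ]), 0.7,
               tolerance = 1e-12)
  m <- matchDetections(pred, gt, 0.5)
  expect_identical(nrow(m$tp), 1L)
  # empty predictions: all ground truths are misses
  m2 <- matchDetections(DetectionSet(0L, dims = c(H, W)),
                        mk(c(2L, 3L), c(1, 1),
                           rbind(c(0, 0, 0.5, 0.5), c(0.5, 0.5, 1, 1))),
                        0.5)
  expect_identical(nrow(m2$tp), 0L)
  expect_identical(length(m2$fn), 2L)
  # two preds on one gt: the higher score wins, the other is FP
  twoP <- mk(c(2L, 2L), c(0.8, 0.9),
             rbind(c(0, 0, 0.5, 0.5), c(0, 0, 0.5, 0.45)))
  m3 <- matchDetections(twoP, gt, 0.5)
  expect_identical(m3$tp$pred, 2L)
  expect_identical(m3$fp, 1L)
  # class mismatch never matches
  m4 <- matchDetections(mk(3L, 1, rbind(c(0, 0, 0.5, 0.5))), gt, 0.5)
  expect_identical(length(m4$fn), 1L)
})

test_that("matching and reports agree with a brute-force pair oracle", {
  set.seed(55)
  for (rep in 1:100) {
    np <- sample(0:5, 1); ng <- sample(0:5, 1)
    preds <- randomDetections(0L, np)
    gts <- randomDetections(0L, ng)
    gts@scores <- rep(1, ng)
    m <- matchDetections(preds, gts, 0.5)
    bf <- bfMatch(list(classes = preds@classIds, scores = preds@scores,
                       boxes = preds@boxes),
                  list(classes = gts@classIds, boxes = gts@boxes), 0.5)
    expect_identical(nrow(m$tp), if (is.null(bf$tp)) 0L else nrow(bf$tp))
    expect_identical(length(m$fp), as.integer(bf$fp))
    expect_identical(length(m$fn), as.integer(bf$fn))
    if (nrow(m$tp))
      expect_lt(max(abs(sort(m$tp$iou) - sort(bf$tp[, 3]))), 1e-12)
  }
})

test_that("the detection report reproduces its formulas on constructed counts", {
  b <- demoScene(T = 6, entry = 0)
  gts <- b@detections
  # perfect detector: everything 1
  perfect <- detectionReport(gts, gts)
  expect_identical(perfect@classF1, 1)
  expect_identical(perfect@bbIoU, 1)
  expect_identical(perfect@maskDice, 1)
  expect_identical(perfect@semanticDice, 1)
  # drop one ground truth from the predictions of frame 0: 3 gts per frame,
  # frame 0 contributes 2 TP + 1 FN
  d0 <- gts[[1]]
  preds <- gts
  preds[[1]] <- DetectionSet(0L, d0@classIds[-1], d0@scores[-1],
                             d0@boxes[-1, , drop = FALSE], d0@masks[-1],
                             dims = d0@dims)
  rep1 <- detectionReport(preds[1], gts[1])
  expect_equal(rep1@classF1, 2 * 2 / (2 * 2 + 0 + 1))
  # mean box IoU over TPs with constructed IoUs 0.6 and 0.8
  mkBox <- function(b1, b2) DetectionSet(0L, c(2L, 3L), c(1, 1),
    rbind(b1, b2), replicate(2, matrix(1, 8, 8), simplify = FALSE),
    dims = c(8, 8))
  gt2 <- mkBox(c(0, 0, 0.5, 0.5), c(0.5, 0.5, 1, 1))
  pr2 <- mkBox(c(0, 0, 0.5, 0.35), c(0.5, 0.5, 1, 0.95))
  got <- detectionReport(list(pr2), list(gt2))
  iou1 <- boxIoU(pr2@boxes[1, ], gt2@boxes[1, ])
  iou2 <- boxIoU(pr2@boxes[2, ], gt2@boxes[2, ])
  expect_equal(got@bbIoU, mean(c(iou1, iou2)), tolerance = 1e-12)
  # vacuous case warns and reports ones
  empty <- list(DetectionSet(0L, dims = c(8, 8)))
  expect_warning(v <- detectionReport(empty, empty), "vacuously")
  expect_identical(v@classF1, 1)
})

test_that("the detection report is invariant to detection list order", {
  set.seed(66)
  preds <- randomDetections(0L, 5)
  gts <- randomDetections(0L, 4)
  gts@scores <- rep(1, 4)
  perm <- sample(5)
  preds2 <- DetectionSet(0L, preds@classIds[perm], preds@scores[perm],
                         preds@boxes[perm, , drop = FALSE],
                         preds@masks[perm], dims = preds@dims)
  a <- detectionReport(list(preds), list(gts))
  b <- detectionReport(list(preds2), list(gts))
  expect_equal(a@classF1, b@classF1)
  expect_equal(a@bbIoU, b@bbIoU)
  expect_equal(a@semanticDice, b@semanticDice)
})
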