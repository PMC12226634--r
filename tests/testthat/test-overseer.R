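# Overseer contract, semantic mask rendering, class sets and the
# multi-task detection loss.

test_that("the noiseless oracle reproduces detections from the ground-truth mask", {
  b <- demoScene(T = 10)
  ov <- OracleOverseer(b)
  for (t in c(0, 5, 9)) {
    d <- detect(ov, getFrame(b@frames, t), t)
    ref <- detectionsFromMask(getMask(b@masks, t), b@schema, t)
    expect_identical(d@classIds, ref@classIds)
    expect_equal(d@boxes, ref@boxes)
  }
  expect_error(detect(ov, getFrame(b@frames, 0), 99), "unknown frame")
  expect_error(detect(ov, array(0L, c(4, 4, 3)), 0), "configured")
})

test_that("a full-miss oracle returns empty detections on every frame", {
  b <- demoScene(T = 6)
  ov <- OracleOverseer(b@masks, b@schema, NoiseConfig(missProb = 1, seed = 1))
  for (t in 0:5)
    expect_identical(nDetections(detect(ov, getFrame(b@frames, t), t)), 0L)
})

test_that("semantic rendering resolves overlaps by score then list index", {
  H <- 6; W <- 6
  m1 <- matrix(0, H, W); m1[2:4, 2:4] <- 1
  m2 <- matrix(0, H, W); m2[3:5, 3:5] <- 1
  d <- DetectionSet(0L, c(3L, 5L), c(0.9, 0.6),
                    rbind(c(0.1, 0.1, 0.7, 0.7), c(0.3, 0.3, 0.9, 0.9)),
                    list(m1, m2), dims = c(H, W))
  sem <- semanticMaskFromDetections(d)
  # pixel-wise enumeration oracle
  for (r in 1:H) for (cc in 1:W) {
    covering <- c(if (m1[r, cc]) 1L, if (m2[r, cc]) 2L)
    want <- if (!length(covering)) 0L
    else d@classIds[covering[which.max(d@scores[covering])]]
    expect_identical(sem[r, cc], want)
  }
  # equal scores: the lower detection index wins
  dTie <- DetectionSet(0L, c(3L, 5L), c(0.8, 0.8), d@boxes, list(m1, m2),
                       dims = c(H, W))
  semTie <- semanticMaskFromDetections(dTie)
  expect_identical(semTie[3, 3], 3L)
  # empty and single-instance cases
  expect_identical(semanticMaskFromDetections(DetectionSet(0L,
                     dims = c(H, W))), matrix(0L, H, W))
  single <- semanticMaskFromDetections(DetectionSet(0L, 4L, 1,
              rbind(c(0.1, 0.1, 0.7, 0.7)), list(m1), dims = c(H, W)))
  expect_identical(single, matrix(4L, H, W) * (m1 == 1)
                   + matrix(0L, H, W))
})

test_that("rendering detections of a mask with disjoint components recovers the mask", {
  schema <- LabelSchema(c("a", "b", "c"))
  set.seed(21)
  for (rep in 1:20) {
    m <- matrix(0L, 8, 8)
    for (cls in sample(1:3, 2)) {
      r0 <- sample(1:5, 1); c0 <- sample(1:5, 1)
      m[r0:(r0 + 2), c0:(c0 + 2)] <- cls   # later square may overwrite
    }
    d <- detectionsFromMask(m, schema)
    expect_identical(semanticMaskFromDetections(d), m)
  }
})

test_that("class sets deduplicate and respect the score threshold", {
  d <- DetectionSet(0L, c(2L, 2L, 5L), c(0.9, 0.8, 0.7),
                    rbind(c(0, 0, 0.5, 0.5), c(0.5, 0.5, 1, 1),
                          c(0, 0.5, 0.5, 1)),
                    replicate(3, matrix(1, 4, 4), simplify = FALSE),
                    dims = c(4, 4))
  expect_identical(classSet(d, 0.5), c(2L, 5L))
  d@scores[3] <- 0.3
  expect_identical(classSet(d, 0.5), 2L)
  expect_identical(classSet(DetectionSet(0L, dims = c(4, 4))), integer(0))
})

test_that("class cross-entropy matches its closed forms", {
  # perfect one-hot prediction: zero up to the clipping bound
  p <- rbind(c(1, 0, 0, 0), c(0, 0, 1, 0))
  expect_lt(lossCls(p, p), 1e-6)
  # uniform prediction over C = 4: ln 4 regardless of the target
  u <- matrix(1 / 4, 2, 4)
  expect_equal(lossCls(u, p), log(4), tolerance = 1e-9)
  # averaging over objects: (0 + ln 4) / 2
  mix <- rbind(c(1, 0, 0, 0), rep(1 / 4, 4))
  expect_equal(lossCls(mix, p), log(4) / 2, tolerance = 1e-6)
  expect_error(lossCls(u, p[, 1:3]), "shape mismatch")
})

test_that("smooth-L1 box loss matches its piecewise closed form", {
  t0 <- rbind(c(0.1, 0.1, 0.6, 0.6))
  expect_identical(lossBox(t0, t0), 0)
  # all four coordinate differences 0.5: 4 * 0.125
  expect_equal(lossBox(t0, t0 + 0.5), 0.5, tolerance = 1e-12)
  # continuity at |d| = 1: both branches give 0.5 per coordinate
  d <- rbind(c(1, 0, 0, 0))
  expect_equal(lossBox(d, d * 0), 0.5, tolerance = 1e-12)
  eps <- 1e-9
  expect_equal(lossBox(rbind(c(1 - eps, 0, 0, 0)), d * 0),
               lossBox(rbind(c(1 + eps, 0, 0, 0)), d * 0),
               tolerance = 1e-6)
})

test_that("box loss is monotone in the per-coordinate deviation", {
  set.seed(8)
  for (rep in 1:50) {
    d1 <- runif(1, 0, 2); d2 <- d1 + runif(1, 0.01, 1)
    l1 <- lossBox(rbind(c(d1, 0, 0, 0)), rbind(rep(0, 4)))
    l2 <- lossBox(rbind(c(d2, 0, 0, 0)), rbind(rep(0, 4)))
    expect_gt(l2, l1)
  }
})

test_that("mask cross-entropy matches hand-evaluated values", {
  m <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_lt(lossMask(m, m), 1e-6)
  expect_equal(lossMask(matrix(0.5, 3, 3), matrix(1, 3, 3)), log(2),
               tolerance = 1e-9)
  # 2x1 mask, m = (0.9, 0.2), m* = (1, 0)
  expect_equal(lossMask(matrix(c(0.9, 0.2), 2, 1),
                        matrix(c(1, 0), 2, 1)),
               (-log(0.9) - log(0.8)) / 2, tolerance = 1e-12)
  expect_error(lossMask(matrix(0.5, 2, 2), matrix(1, 3, 3)),
               "shape mismatch")
})

test_that("the multi-task loss is the sum of its averaged parts", {
  p <- rbind(c(1, 0, 0, 0))
  perfect <- list(p = p, boxes = rbind(rep(0.2, 4)),
                  masks = list(matrix(c(1, 0), 2, 2)))
  fit <- multitaskLoss(perfect, perfect)
  expect_lt(fit@total, 3e-6)

  preds <- list(p = rbind(rep(1 / 2, 2)), boxes = rbind(rep(0.5, 4)),
                masks = list(matrix(0.5, 2, 2)))
  targets <- list(p = rbind(c(1, 0)), boxes = rbind(rep(0, 4)),
                  masks = list(matrix(1, 2, 2)))
  fit2 <- multitaskLoss(preds, targets)
  expect_equal(fit2@cls, log(2), tolerance = 1e-9)
  expect_equal(fit2@box, 0.5, tolerance = 1e-12)
  expect_equal(fit2@mask, log(2), tolerance = 1e-9)
  expect_equal(fit2@total, fit2@cls + fit2@box + fit2@mask)

  expect_error(multitaskLoss(list(p = matrix(numeric(0), 0, 2)),
                             list(p = matrix(numeric(0), 0, 2))),
               "no objects to score")
})

test_that("non-negative losses vanish only for matching inputs", {
  set.seed(31)
  for (rep in 1:25) {
    C <- 4
    p <- matrix(runif(C), 1); p <- p / sum(p)
    tgt <- diag(C)[sample(C, 1), , drop = FALSE]
    expect_gte(lossCls(p, tgt), 0)
    m <- matrix(runif(9), 3, 3)
    ms <- matrix(rbinom(9, 1, 0.5), 3, 3)
    expect_gte(lossMask(m, ms), 0)
    if (any(abs(m - ms) > 0.01))
      expect_gt(lossMask(m, ms), 1e-4)
  }
})

test_that("detection sets round-trip through the RLE text format", {
  b <- demoScene(T = 4)
  path <- withr::local_tempfile(fileext = ".txt")
  writeDetections(b@detections, path)
  back <- readDetections(path)
  expect_identical(length(back), 4L)
  for (t in 1:4) {
    expect_identical(back[[t]]@classIds, b@detections[[t]]@classIds)
    expect_equal(back[[t]]@boxes, b@detections[[t]]@boxes)
    expect_equal(lapply(back[[t]]@masks, function(m) m >= 0.5),
                 lapply(b@detections[[t]]@masks, function(m) m >= 0.5))
  }
})
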