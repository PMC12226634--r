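# Anchor sampling, the persistence rule on the class buffer, and the
# orchestrated re-prompting loop.

test_that("the anchor of a filled disk is its centre", {
  m <- matrix(0L, 33, 33)
  m[(row(m) - 17)^2 + (col(m) - 17)^2 <= 64] <- 2L
  a <- sampleAnchorPoints(m)
  expect_identical(nrow(a), 1L)
  expect_identical(c(a$row, a$col), c(16L, 16L))   # 0-based centre
  # brute-force check: no pixel of the disk is deeper
  d <- matrix(Inf, 33, 33)
  bg <- which(m == 0L, arr.ind = TRUE)
  for (p in which(m == 2L)) {
    r <- (p - 1) %% 33 + 1; cc <- (p - 1) %/% 33 + 1
    d[r, cc] <- min(sqrt((bg[, 1] - r)^2 + (bg[, 2] - cc)^2))
  }
  expect_equal(d[a$row + 1, a$col + 1], max(d[m == 2L]), tolerance = 1e-9)
})

test_that("each disjoint component yields one interior anchor", {
  m <- matrix(0L, 16, 16)
  m[2:5, 2:5] <- 3L
  m[10:14, 9:15] <- 3L
  a <- sampleAnchorPoints(m)
  expect_identical(nrow(a), 2L)
  lab <- bfComponents8(m == 3L)
  for (i in 1:2)
    expect_identical(lab[a$row[i] + 1, a$col[i] + 1], a$component[i])
  # anchors lie inside their components
  expect_true(all(m[cbind(a$row + 1, a$col + 1)] == 3L))
  # requesting an absent class errors
  expect_error(sampleAnchorPoints(m, classes = 5L), "empty class")
  expect_error(sampleAnchorPoints(matrix(0L, 4, 4), classes = 1L),
               "empty class")
})

test_that("extra anchors are distinct interior local maxima", {
  m <- matrix(0L, 12, 24)
  m[4:9, 3:10] <- 1L
  m[4:9, 15:22] <- 1L   # two lobes joined by a thin bridge
  m[6:7, 11:14] <- 1L
  a <- sampleAnchorPoints(m, k = 2L)
  expect_identical(a$component, c(1L, 1L))
  expect_identical(anyDuplicated(a[, c("row", "col")]), 0L)
  expect_true(all(m[cbind(a$row + 1, a$col + 1)] == 1L))
})

test_that("the persistence rule triggers only after nT + 1 discrepant frames", {
  ref <- c(1L, 2L)
  mkBuffer <- function(sets, start = 1L) {
    buf <- ClassBuffer(referenceSet = ref)
    for (i in seq_along(sets))
      buf <- bufferAppend(buf, start + i - 1L, sets[[i]])
    buf
  }
  # constant sets never trigger
  buf <- mkBuffer(rep(list(ref), 10))
  for (t in 1:10) expect_null(detectPersistentChange(buf, 4L, t))
  # a 3-frame discrepancy is suppressed at nT = 4
  sets <- c(rep(list(ref), 4), rep(list(c(1L, 2L, 5L)), 3),
            rep(list(ref), 3))
  buf <- mkBuffer(sets)
  for (t in 1:10) expect_null(detectPersistentChange(buf, 4L, t))
  # a discrepancy starting at frame 20 triggers at t' = 24, back-track 20
  buf2 <- ClassBuffer(referenceSet = ref)
  for (t in 15:24)
    buf2 <- bufferAppend(buf2, t, if (t >= 20) c(1L, 2L, 3L) else ref)
  for (t in 15:23) expect_null(detectPersistentChange(buf2, 4L, t))
  trig <- detectPersistentChange(buf2, 4L, 24L)
  expect_identical(trig, list(tPrime = 24L, backtrack = 20L))
  # drifting discrepant sets still count as one persistent run
  buf3 <- ClassBuffer(referenceSet = ref)
  drift <- list(c(1L, 2L, 5L), c(1L, 2L, 6L), c(1L, 2L, 5L),
                c(1L, 2L, 7L), 1L)
  for (i in seq_along(drift)) buf3 <- bufferAppend(buf3, i, drift[[i]])
  expect_identical(detectPersistentChange(buf3, 4L, 5L)$backtrack, 1L)
})

test_that("a stable scene with a perfect overseer never re-prompts", {
  b <- demoScene(T = 20, entry = 0, exit = 20)
  run <- runReprompt(b@frames, OracleOverseer(b),
                     FlowPropagationTracker(frameDims(b), b@flow),
                     b@schema)
  expect_identical(nrow(run@log), 0L)
  expect_identical(run@promptFrame, 0L)
  expect_identical(nFrames(run@masks), 20L)
  # matches the tracker-only output
  for (t in 0:19)
    expect_identical(getMask(run@masks, t), getMask(b@masks, t))
})

test_that("static scenes give identical output masks on every frame", {
  b <- demoScene(T = 10, entry = 0, exit = 10, velocity = c(0, 0))
  run <- runReprompt(b@frames, OracleOverseer(b),
                     FlowPropagationTracker(frameDims(b), b@flow),
                     b@schema)
  for (t in 1:9)
    expect_identical(getMask(run@masks, t), getMask(run@masks, 0))
})

test_that("an entering object is recovered from its entry frame onward", {
  b <- demoScene(T = 40, entry = 12)
  run <- runReprompt(b@frames, OracleOverseer(b),
                     FlowPropagationTracker(frameDims(b), b@flow),
                     b@schema)
  expect_identical(nrow(run@log), 1L)
  expect_identical(run@log$trigger_frame, 16L)
  expect_identical(run@log$reprompt_frame, 12L)
  for (t in 0:39)
    expect_identical(3L %in% classesInMask(getMask(run@masks, t)), t >= 12)
})

test_that("a leaving object is erased from the back-tracked outputs", {
  b <- demoScene(T = 40, entry = 0, exit = 25)
  run <- runReprompt(b@frames, OracleOverseer(b),
                     FlowPropagationTracker(frameDims(b), b@flow),
                     b@schema)
  expect_identical(nrow(run@log), 1L)
  expect_identical(run@log$reprompt_frame, 25L)
  for (t in 25:39)
    expect_false(3L %in% classesInMask(getMask(run@masks, t)))
})

test_that("the initial prompt is deferred until the overseer sees an entity", {
  schema <- LabelSchema(c("a", "b"))
  cfg <- SceneConfig(32, 32, 20, schema, objects = list(
    ObjectSpec(2, "disk", center = c(16, 16), velocity = c(0, 0),
               entryFrame = 6, exitFrame = 20, radius = 5)))
  b <- generateScene(cfg)
  run <- runReprompt(b@frames, OracleOverseer(b),
                     FlowPropagationTracker(frameDims(b), b@flow), schema)
  expect_identical(run@promptFrame, 6L)
  expect_true(any(grepl("deferred to frame 6", run@notes)))
  for (t in 0:5)
    expect_identical(getMask(run@masks, t), matrix(0L, 32, 32))
  for (t in 6:19)
    expect_identical(getMask(run@masks, t), getMask(b@masks, t))
})

test_that("orchestration output is bit-deterministic", {
  b <- demoScene(T = 25, entry = 8)
  runs <- lapply(1:2, function(i)
    runReprompt(b@frames, OracleOverseer(b),
                FlowPropagationTracker(frameDims(b), b@flow), b@schema))
  expect_identical(runs[[1]]@masks@masks, runs[[2]]@masks@masks)
  expect_identical(runs[[1]]@log, runs[[2]]@log)
})

test_that("re-prompt logs round-trip through their text format", {
  log <- data.frame(trigger_frame = c(24L, 40L), reprompt_frame = c(20L, 36L),
                    old_classes = c("1,2", ""), new_classes = c("1,2,3", "1"))
  path <- withr::local_tempfile(fileext = ".txt")
  writeRepromptLog(log, path)
  expect_identical(readRepromptLog(path), log)
})
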