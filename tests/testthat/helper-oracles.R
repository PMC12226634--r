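# Independent brute-force oracles used to check the vectorised metric and
# labelling implementations. These deliberately use naive per-pixel loops and
# never call the package functions they verify.

# flood-fill 8-connected labelling
bfComponents8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; cc <- p[2] + dc
        if (r < 1 || r > H || cc < 1 || cc > W) next
        if (mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- nxt
          queue <- c(queue, list(c(r, cc)))
        }
      }
    }
  }
  lab
}

# per-class pixel-set dice/iou by direct enumeration
bfOverlap <- function(a, b, cls) {
  A <- which(a == cls); B <- which(b == cls)
  inter <- length(intersect(A, B))
  dice <- 2 * inter / (length(A) + length(B))
  iou <- inter / length(union(A, B))
  c(dice = dice, iou = iou)
}

bfMacroOverlap <- function(a, b) {
  ids <- sort(unique(c(as.vector(a), as.vector(b))))
  m <- sapply(ids, function(cls) bfOverlap(a, b, cls))
  c(dice = mean(m["dice", ]), iou = mean(m["iou", ]))
}

# boundary pixels by per-pixel neighbour inspection
bfBoundary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- NULL
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    if (!m[r, cc]) next
    edge <- r == 1 || r == H || cc == 1 || cc == W
    if (!edge)
      edge <- !m[r - 1, cc] || !m[r + 1, cc] || !m[r, cc - 1] ||
        !m[r, cc + 1]
    if (edge) out <- rbind(out, c(r, cc))
  }
  out
}

bfContourDistance <- function(a, b) {
  ids <- sort(setdiff(unique(c(as.vector(a), as.vector(b))), 0L))
  if (!length(ids)) return(NA_real_)
  diagPen <- sqrt(nrow(a)^2 + ncol(a)^2)
  vals <- numeric(0)
  for (cls in ids) {
    inA <- any(a == cls); inB <- any(b == cls)
    if (inA && inB) {
      ba <- bfBoundary(a == cls); bb <- bfBoundary(b == cls)
      dAB <- mean(apply(ba, 1, function(p)
        min(sqrt((bb[, 1] - p[1])^2 + (bb[, 2] - p[2])^2))))
      dBA <- mean(apply(bb, 1, function(p)
        min(sqrt((ba[, 1] - p[1])^2 + (ba[, 2] - p[2])^2))))
      vals <- c(vals, (dAB + dBA) / 2)
    } else vals <- c(vals, diagPen)
  }
  mean(vals)
}

bfBoxIoU <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  if (inter == 0) return(0)
  inter / ((a[3] - a[1]) * (a[4] - a[2]) +
           (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# greedy matching re-implemented independently from explicit loops
bfMatch <- function(preds, gts, thr) {
  cand <- NULL
  for (i in seq_along(preds$classes)) for (j in seq_along(gts$classes)) {
    if (preds$classes[i] != gts$classes[j]) next
    iou <- bfBoxIoU(preds$boxes[i, ], gts$boxes[j, ])
    if (iou >= thr) cand <- rbind(cand, c(i, j, iou, preds$scores[i]))
  }
  tp <- NULL
  usedP <- rep(FALSE, length(preds$classes))
  usedG <- rep(FALSE, length(gts$classes))
  while (!is.null(cand) && nrow(cand)) {
    best <- order(-cand[, 4], -cand[, 3], cand[, 1], cand[, 2])[1]
    i <- cand[best, 1]; j <- cand[best, 2]
    tp <- rbind(tp, cand[best, , drop = FALSE])
    usedP[i] <- TRUE; usedG[j] <- TRUE
    cand <- cand[cand[, 1] != i & cand[, 2] != j, , drop = FALSE]
  }
  list(tp = tp, fp = sum(!usedP), fn = sum(!usedG))
}

# random small label map with blobby structure
randomMask <- function(H = 8, W = 8, C = 3) {
  m <- matrix(sample(0:C, H * W, replace = TRUE, prob = c(0.55,
              rep(0.45 / C, C))), H, W)
  m
}

# random detection set over an 8x8 frame
randomDetections <- function(frameId, n, C = 3, H = 8, W = 8) {
  if (n == 0L) return(DetectionSet(frameId, dims = c(H, W)))
  classIds <- sample(seq_len(C), n, replace = TRUE)
  scores <- round(stats::runif(n), 3)
  boxes <- t(replicate(n, {
    r <- sort(sample(0:H, 2)); cc <- sort(sample(0:W, 2))
    while (r[1] == r[2]) r <- sort(sample(0:H, 2))
    while (cc[1] == cc[2]) cc <- sort(sample(0:W, 2))
    c(cc[1] / W, r[1] / H, cc[2] / W, r[2] / H)
  }))
  masks <- lapply(seq_len(n), function(i) {
    m <- matrix(0, H, W)
    rows <- (round(boxes[i, 2] * H) + 1):round(boxes[i, 4] * H)
    cols <- (round(boxes[i, 1] * W) + 1):round(boxes[i, 3] * W)
    m[rows, cols] <- 1
    m
  })
  DetectionSet(frameId, classIds, scores, boxes, masks, dims = c(H, W))
}

# standard small scene used by several tests: static background strip
# (class 1), a static disk (class 2) and a moving rectangle (class 3)
# entering at `entry` and leaving at `exit`
demoScene <- function(T = 60, entry = min(20, T %/% 2), exit = T, H = 64,
                      W = 64, velocity = c(0, 1)) {
  schema <- LabelSchema(c("tissue", "grasper", "hook"))
  cfg <- SceneConfig(H, W, T, schema,
    objects = list(
      ObjectSpec(2, "disk", center = c(20, 16), velocity = c(0, 0),
                 entryFrame = 0, exitFrame = T, radius = 6),
      ObjectSpec(3, "rectangle", center = c(44, 12), velocity = velocity,
                 entryFrame = entry, exitFrame = exit, height = 9,
                 width = 7)),
    backgroundRegions = list(
      ObjectSpec(1, "rectangle", center = c(H - 6, W %/% 2), height = 12,
                 width = W, exitFrame = T)))
  generateScene(cfg)
}

classesInMask <- function(mask) sort(setdiff(unique(as.vector(mask)), 0L))
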