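# Per-frame detection and segmentation metrics: greedy matching at a box-IoU
# threshold, pooled class F1, mean box IoU, instance-mask Dice at 50% IoU
# and semantic Dice of rendered label maps.

#' Intersection-over-union of two normalised boxes
#'
#' Boxes are half-open \code{(x_min, y_min, x_max, y_max)} in \eqn{[0,1]^4}.
#'
#' @param a,b numeric length-4 boxes.
#' @return IoU in \eqn{[0,1]}.
#' @export
boxIoU <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  areaA <- (a[3] - a[1]) * (a[4] - a[2])
  areaB <- (b[3] - b[1]) * (b[4] - b[2])
  if (inter == 0) return(0)
  inter / (areaA + areaB - inter)
}

#' Greedy matching of predicted to ground-truth detections
#'
#' Candidate pairs share the class and have box IoU >= the threshold; they
#' are consumed in order of descending prediction score, then descending
#' IoU (then prediction and ground-truth index for determinism), each
#' prediction and ground truth matched at most once. Unmatched predictions
#' are false positives, unmatched ground truths false negatives.
#'
#' @param preds,gts [DetectionSet] objects for one frame.
#' @param iouThreshold box IoU threshold in (0, 1); default 0.5.
#' @return list with \code{tp} (data.frame pred, gt, iou; 1-based indices),
#'   \code{fp} and \code{fn} (integer index vectors).
#' @export
matchDetections <- function(preds, gts, iouThreshold = 0.5) {
  if (iouThreshold <= 0 || iouThreshold >= 1)
    stop("iouThreshold must be in (0, 1)", call. = FALSE)
  np <- nDetections(preds); ng <- nDetections(gts)
  cand <- NULL
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    if (preds@classIds[i] != gts@classIds[j]) next
    iou <- boxIoU(preds@boxes[i, ], gts@boxes[j, ])
    if (iou >= iouThreshold)
      cand <- rbind(cand, c(i, j, iou, preds@scores[i]))
  }
  tp <- data.frame(pred = integer(0), gt = integer(0), iou = numeric(0))
  usedP <- logical(np); usedG <- logical(ng)
  if (!is.null(cand)) {
    ord <- order(-cand[, 4], -cand[, 3], cand[, 1], cand[, 2])
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (usedP[i] || usedG[j]) next
      usedP[i] <- TRUE; usedG[j] <- TRUE
      tp <- rbind(tp, data.frame(pred = as.integer(i), gt = as.integer(j),
                                 iou = cand[k, 3]))
    }
  }
  list(tp = tp, fp = which(!usedP), fn = which(!usedG))
}

maskOverlapStats <- function(mp, mg) {
  A <- mp >= 0.5; B <- mg >= 0.5
  inter <- sum(A & B); sa <- sum(A); sb <- sum(B)
  c(iou = if (sa + sb - inter > 0) inter / (sa + sb - inter) else 1,
    dice = if (sa + sb > 0) 2 * inter / (sa + sb) else 1)
}

#' Per-frame detection and segmentation report
#'
#' Pools greedy matches at 50\% box IoU over all frames and reports:
#' class F1 = 2TP / (2TP + FP + FN); mean box IoU over true-positive pairs;
#' mean instance-mask Dice over true positives whose mask IoU is >= 0.5;
#' and the semantic Dice — the per-frame macro Dice of the rendered semantic
#' masks of predictions and ground truths, averaged over frames. When there
#' are no ground truths and no predictions anywhere the report is vacuously
#' perfect (all 1) and a warning is raised.
#'
#' @param preds,gts lists of [DetectionSet], aligned frame by frame.
#' @param iouThreshold box IoU threshold (default 0.5).
#' @return a [DetectionReport].
#' @export
detectionReport <- function(preds, gts, iouThreshold = 0.5) {
  if (length(preds) != length(gts))
    stop(sprintf("length mismatch: %d prediction frames but %d ground-truth frames",
                 length(preds), length(gts)), call. = FALSE)
  tp <- 0L; fp <- 0L; fn <- 0L
  bbIoUs <- numeric(0)
  maskDices <- numeric(0)
  semDices <- numeric(0)
  for (t in seq_along(preds)) {
    m <- matchDetections(preds[[t]], gts[[t]], iouThreshold)
    tp <- tp + nrow(m$tp); fp <- fp + length(m$fp); fn <- fn + length(m$fn)
    bbIoUs <- c(bbIoUs, m$tp$iou)
    for (k in seq_len(nrow(m$tp))) {
      st <- maskOverlapStats(preds[[t]]@masks[[m$tp$pred[k]]],
                             gts[[t]]@masks[[m$tp$gt[k]]])
      if (st["iou"] >= 0.5) maskDices <- c(maskDices, st["dice"])
    }
    semDices <- c(semDices,
                  macroOverlap(semanticMaskFromDetections(preds[[t]]),
                               semanticMaskFromDetections(gts[[t]]))$dice)
  }
  if (tp + fp + fn == 0L) {
    warning("no detections and no ground truths: vacuously perfect report")
    return(new("DetectionReport", classF1 = 1, bbIoU = 1, maskDice = 1,
               semanticDice = 1, counts = c(tp = 0, fp = 0, fn = 0)))
  }
  new("DetectionReport",
      classF1 = 2 * tp / (2 * tp + fp + fn),
      bbIoU = if (length(bbIoUs)) mean(bbIoUs) else NA_real_,
      maskDice = if (length(maskDices)) mean(maskDices) else NA_real_,
      semanticDice = mean(semDices),
      counts = c(tp = tp, fp = fp, fn = fn))
}

setMethod("show", "DetectionReport", function(object) {
  cat(sprintf(paste0("DetectionReport: class F1 %.3f, BB IoU %.3f, mask ",
                     "Dice %.3f, semantic Dice %.3f (TP %d / FP %d / FN ",
                     "%d)\n"),
              object@classF1, object@bbIoU, object@maskDice,
              object@semanticDice, object@counts["tp"],
              object@counts["fp"], object@counts["fn"]))
})
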