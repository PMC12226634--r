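# Overlap and temporal-consistency metrics: macro Dice/IoU, symmetric
# contour distance, and the per-pair consistency report combining
# flow-warped and direct inter-frame comparisons.

#' Macro-averaged Dice and IoU of two label maps
#'
#' Per class c, Dice = 2|A∩B| / (|A|+|B|) and IoU = |A∩B| / |A∪B| over the
#' class's pixel sets; the macro score is the unweighted mean over the
#' included classes. By default (\code{classes = "present"}) every class
#' present in either mask is included — background included, classes absent
#' from both excluded, and a class present in exactly one mask scores 0.
#' With \code{classes = "all"} every schema class is included and classes
#' absent from both masks score 1 (perfect agreement on absence).
#'
#' @param maskA,maskB integer label maps of equal shape.
#' @param schema [LabelSchema], required for \code{classes = "all"}.
#' @param classes \code{"present"} or \code{"all"}.
#' @return list with \code{dice}, \code{iou} (macro means) and
#'   \code{perClass} (data.frame class_id, dice, iou).
#' @export
macroOverlap <- function(maskA, maskB, schema = NULL,
                         classes = c("present", "all")) {
  classes <- match.arg(classes)
  stopShape(identical(dim(maskA), dim(maskB)),
            "shape mismatch between the two masks")
  ids <- if (classes == "all") {
    if (is.null(schema)) stop("schema required for classes = 'all'",
                              call. = FALSE)
    schema@ids
  } else sort(unique(c(as.integer(maskA), as.integer(maskB))))
  per <- data.frame(class_id = ids, dice = NA_real_, iou = NA_real_)
  for (i in seq_along(ids)) {
    A <- maskA == ids[i]; B <- maskB == ids[i]
    sa <- sum(A); sb <- sum(B)
    if (sa + sb == 0L) {
      per$dice[i] <- 1; per$iou[i] <- 1
      next
    }
    inter <- sum(A & B)
    per$dice[i] <- 2 * inter / (sa + sb)
    per$iou[i] <- inter / (sa + sb - inter)
  }
  list(dice = mean(per$dice), iou = mean(per$iou), perClass = per)
}

# boundary pixels of a binary class mask: pixels of the class 4-adjacent to
# a different label or to the frame edge; returns (row, col) matrix
boundaryPixels <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  inner <- pad[2:(H + 1L), 2:(W + 1L), drop = FALSE] &
    pad[1:H, 2:(W + 1L), drop = FALSE] &
    pad[3:(H + 2L), 2:(W + 1L), drop = FALSE] &
    pad[2:(H + 1L), 1:W, drop = FALSE] &
    pad[2:(H + 1L), 3:(W + 2L), drop = FALSE]
  which(m & !inner, arr.ind = TRUE)
}

meanNearestDistance <- function(a, b) {
  # mean over rows of `a` of the Euclidean distance to the nearest row of `b`
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  mean(sqrt(apply(d2, 1, min)))
}

#' Macro-averaged symmetric contour distance of two label maps
#'
#' Per non-background class present in both masks: the mean over boundary
#' pixels of A of the distance to the nearest boundary pixel of B, averaged
#' with the reverse direction. A class present in exactly one mask
#' contributes the frame diagonal \eqn{\sqrt{H^2+W^2}} as a flicker penalty
#' (the metric is deliberately sensitive to appearing/vanishing classes);
#' with \code{flickerPenalty = FALSE} such classes are skipped instead.
#' Boundaries are pixels 4-adjacent to a different label or the frame edge.
#'
#' @param maskA,maskB integer label maps of equal shape.
#' @param flickerPenalty whether one-sided classes contribute the diagonal.
#' @return macro-averaged distance in pixels, or \code{NA} with attribute
#'   \code{"no_contours"} when both masks are entirely background.
#' @export
contourDistance <- function(maskA, maskB, flickerPenalty = TRUE) {
  stopShape(identical(dim(maskA), dim(maskB)),
            "shape mismatch between the two masks")
  inA <- setdiff(unique(as.integer(maskA)), 0L)
  inB <- setdiff(unique(as.integer(maskB)), 0L)
  ids <- sort(union(inA, inB))
  if (!length(ids)) {
    out <- NA_real_
    attr(out, "no_contours") <- TRUE
    return(out)
  }
  diag <- sqrt(nrow(maskA)^2 + ncol(maskA)^2)
  vals <- numeric(0)
  for (cls in ids) {
    if (cls %in% inA && cls %in% inB) {
      ba <- boundaryPixels(maskA == cls)
      bb <- boundaryPixels(maskB == cls)
      vals <- c(vals, (meanNearestDistance(ba, bb) +
                       meanNearestDistance(bb, ba)) / 2)
    } else if (flickerPenalty) {
      vals <- c(vals, diag)
    }
  }
  if (!length(vals)) {
    out <- NA_real_
    attr(out, "no_contours") <- TRUE
    return(out)
  }
  mean(vals)
}

#' Temporal-consistency report of a mask sequence
#'
#' For every frame pair (t, t+1): the macro Dice and IoU of the previous
#' mask warped along the optical flow against the next mask (warped Dice /
#' IoU — consistency with respect to the actual image motion), the contour
#' distance and the plain macro IoU of the two masks (consistency ignoring
#' image content). Sequence values are means over the T-1 pairs; contour
#' distances of pairs without any contour are excluded from the mean.
#'
#' @param frames a [FrameSequence].
#' @param masks the [MaskSequence] to evaluate (same length).
#' @param flowSource \code{"estimated"} or \code{"ground_truth"}.
#' @param gtFlow list of exact flow fields when
#'   \code{flowSource = "ground_truth"} (e.g. \code{bundle@flow}).
#' @return a [ConsistencyReport].
#' @export
temporalConsistencyReport <- function(frames, masks,
                                      flowSource = c("estimated",
                                                     "ground_truth"),
                                      gtFlow = NULL) {
  flowSource <- match.arg(flowSource)
  T <- nFrames(masks)
  if (nFrames(frames) != T)
    stop(sprintf("length mismatch: %d frames but %d masks",
                 nFrames(frames), T), call. = FALSE)
  if (T < 2L) stop("at least two frames required", call. = FALSE)
  pp <- data.frame(pair = seq_len(T - 1L) - 1L, dice_of = NA_real_,
                   iou_of = NA_real_, cd_t = NA_real_, iou_t = NA_real_)
  for (t in seq_len(T - 1L)) {
    fl <- computeFlow(frames@frames[[t]], frames@frames[[t + 1L]],
                      method = flowSource,
                      gtFlow = if (flowSource == "ground_truth")
                        gtFlow[[t]] else NULL)
    warped <- warpMask(masks@masks[[t]], fl)
    ofl <- macroOverlap(warped, masks@masks[[t + 1L]])
    pp$dice_of[t] <- ofl$dice
    pp$iou_of[t] <- ofl$iou
    pp$cd_t[t] <- contourDistance(masks@masks[[t]], masks@masks[[t + 1L]])
    pp$iou_t[t] <- macroOverlap(masks@masks[[t]],
                                masks@masks[[t + 1L]])$iou
  }
  means <- c(dice_of = mean(pp$dice_of), iou_of = mean(pp$iou_of),
             cd_t = mean(pp$cd_t, na.rm = TRUE), iou_t = mean(pp$iou_t))
  new("ConsistencyReport", perPair = pp, means = means)
}

setMethod("show", "ConsistencyReport", function(object) {
  m <- object@means
  cat(sprintf(paste0("ConsistencyReport over %d pairs: Dice_OF %.3f, ",
                     "IoU_OF %.3f, CD_T %.3f, IoU_T %.3f\n"),
              nrow(object@perPair), m["dice_of"], m["iou_of"], m["cd_t"],
              m["iou_t"]))
})

#' Write a report as key-value text and JSON
#'
#' @param report a [ConsistencyReport] or [DetectionReport].
#' @param path base path; \code{<path>.txt} and \code{<path>.json} are
#'   written.
#' @return named numeric vector of the report's scalar values, invisibly.
#' @export
writeReport <- function(report, path) {
  vals <- if (is(report, "ConsistencyReport")) report@means
  else c(class_f1 = report@classF1, bb_iou = report@bbIoU,
         mask_dice = report@maskDice, semantic_dice = report@semanticDice)
  writeLines(sprintf("%s: %.6f", names(vals), vals),
             paste0(path, ".txt"))
  jsonlite::write_json(as.list(vals), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(vals)
}
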