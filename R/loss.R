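# Multi-task detection loss: class cross-entropy, smooth-L1 box regression
# and per-pixel mask cross-entropy, each averaged over its object count, with
# the total being their sum. Matching of predictions to targets is an input;
# the loss operations assume aligned lists.

LOSS_EPS <- 1e-7

clipProb <- function(p) pmin(1 - LOSS_EPS, pmax(LOSS_EPS, p))

#' Class cross-entropy loss
#'
#' \deqn{\frac{1}{N} \sum_i -\sum_k c^*_{ik} \log p_{ik}}
#' Probabilities are clipped to \eqn{[\epsilon, 1-\epsilon]},
#' \eqn{\epsilon = 10^{-7}}, before the logarithm.
#'
#' @param p numeric \code{N x C} matrix of predicted class probabilities
#'   (rows sum to 1).
#' @param cStar numeric \code{N x C} one-hot target matrix.
#' @return non-negative scalar.
#' @export
lossCls <- function(p, cStar) {
  p <- rbind(p); cStar <- rbind(cStar)
  stopShape(identical(dim(p), dim(cStar)),
            "shape mismatch between p and cStar")
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop("class probability rows must sum to 1", call. = FALSE)
  mean(-rowSums(cStar * log(clipProb(p))))
}

smoothL1 <- function(d) ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5)

#' Smooth-L1 bounding-box regression loss
#'
#' Per object the four coordinate differences are scored with the standard
#' smooth-L1 (transition point 1): \eqn{0.5 d^2} for \eqn{|d| < 1}, else
#' \eqn{|d| - 0.5}; coordinate terms are summed per object and averaged over
#' objects.
#'
#' @param tPred,tStar numeric \code{N x 4} matrices of normalised boxes.
#' @return non-negative scalar.
#' @export
lossBox <- function(tPred, tStar) {
  tPred <- rbind(tPred); tStar <- rbind(tStar)
  stopShape(identical(dim(tPred), dim(tStar)),
            "shape mismatch between predicted and target boxes")
  mean(rowSums(smoothL1(tPred - tStar)))
}

#' Per-pixel mask cross-entropy loss
#'
#' Binary cross-entropy of the predicted probability mask for the target
#' class against the binary target mask, averaged over the H x W pixels and
#' over objects. Probabilities are clipped to \eqn{[\epsilon, 1-\epsilon]}.
#'
#' @param m list (or single matrix) of predicted probability masks in
#'   \eqn{[0,1]}.
#' @param mStar list (or single matrix) of binary target masks.
#' @return non-negative scalar.
#' @export
lossMask <- function(m, mStar) {
  if (is.matrix(m)) m <- list(m)
  if (is.matrix(mStar)) mStar <- list(mStar)
  stopShape(length(m) == length(mStar), "shape mismatch between mask lists")
  per <- vapply(seq_along(m), function(i) {
    stopShape(identical(dim(m[[i]]), dim(mStar[[i]])),
              "shape mismatch between predicted and target masks")
    mp <- clipProb(m[[i]])
    mean(-(mStar[[i]] * log(mp) + (1 - mStar[[i]]) * log(1 - mp)))
  }, numeric(1))
  mean(per)
}

#' Multi-task detection loss
#'
#' Sum of the three averaged terms ([lossCls()], [lossBox()], [lossMask()])
#' on matched prediction/target lists; the matching itself is supplied by the
#' caller, not computed here.
#'
#' @param preds,targets lists with elements \code{p} (\code{N x C} class
#'   probabilities; targets: one-hot), \code{boxes} (\code{N x 4}) and
#'   \code{masks} (list of N masks).
#' @return a [LossBreakdown].
#' @examples
#' p <- rbind(c(1, 0), c(0, 1))
#' masks <- list(matrix(1, 2, 2), matrix(0, 2, 2))
#' fit <- multitaskLoss(list(p = p, boxes = rbind(rep(0.2, 4), rep(0.4, 4)),
#'                           masks = masks),
#'                      list(p = p, boxes = rbind(rep(0.2, 4), rep(0.4, 4)),
#'                           masks = masks))
#' fit@total
#' @export
multitaskLoss <- function(preds, targets) {
  if (!nrow(rbind(preds$p))) stop("no objects to score", call. = FALSE)
  cls <- lossCls(preds$p, targets$p)
  box <- lossBox(preds$boxes, targets$boxes)
  msk <- lossMask(preds$masks, targets$masks)
  new("LossBreakdown", cls = cls, box = box, mask = msk,
      total = cls + box + msk)
}

setMethod("show", "LossBreakdown", function(object) {
  cat(sprintf("LossBreakdown: cls %.4f + box %.4f + mask %.4f = %.4f\n",
              object@cls, object@box, object@mask, object@total))
})
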