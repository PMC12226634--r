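# Optical flow: ground-truth provider pass-through, a dense Horn-Schunck
# estimator, and the nearest-neighbour label warping operator.

#' Compute the optical flow between two frames
#'
#' With \code{method = "ground_truth"} the supplied exact field (from a
#' [SceneBundle]) is validated and returned; with \code{method = "estimated"}
#' a dense classical Horn-Schunck estimate is computed from the pixels.
#' Flow is an \code{H x W x 2} array of (drow, dcol) displacements in pixels
#' mapping frame t coordinates to frame t+1.
#'
#' @param frameT,frameNext \code{H x W x 3} integer arrays.
#' @param method \code{"estimated"} or \code{"ground_truth"}.
#' @param gtFlow the exact field when \code{method = "ground_truth"}.
#' @param alpha Horn-Schunck smoothness weight.
#' @param iterations Horn-Schunck iteration count.
#' @return numeric \code{H x W x 2} flow array.
#' @export
computeFlow <- function(frameT, frameNext,
                        method = c("estimated", "ground_truth"),
                        gtFlow = NULL, alpha = 1, iterations = 80) {
  method <- match.arg(method)
  stopShape(identical(dim(frameT)[1:2], dim(frameNext)[1:2]),
            "shape mismatch between the two frames")
  if (method == "ground_truth") {
    if (is.null(gtFlow))
      stop("no ground-truth flow available", call. = FALSE)
    stopShape(identical(dim(gtFlow)[1:2], dim(frameT)[1:2]),
              "ground-truth flow shape does not match the frames")
    return(gtFlow)
  }
  hornSchunck(grayFrame(frameT), grayFrame(frameNext), alpha, iterations)
}

grayFrame <- function(frame) {
  if (length(dim(frame)) == 3L)
    (frame[, , 1] + frame[, , 2] + frame[, , 3]) / (3 * 255)
  else frame / 255
}

# replicate-padded shift of a matrix by one pixel
shiftEdge <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(H, pmax(1L, seq_len(H) + dr))
  ci <- pmin(W, pmax(1L, seq_len(W) + dc))
  m[ri, ci, drop = FALSE]
}

# classical Horn-Schunck dense flow with Jacobi iterations on the
# 4-neighbour average field
hornSchunck <- function(g1, g2, alpha, iterations) {
  Ir <- (shiftEdge(g1, 1L, 0L) - shiftEdge(g1, -1L, 0L)) / 2
  Ic <- (shiftEdge(g1, 0L, 1L) - shiftEdge(g1, 0L, -1L)) / 2
  It <- g2 - g1
  u <- matrix(0, nrow(g1), ncol(g1))   # drow
  v <- matrix(0, nrow(g1), ncol(g1))   # dcol
  denom <- alpha^2 + Ir^2 + Ic^2
  for (k in seq_len(iterations)) {
    ub <- (shiftEdge(u, 1L, 0L) + shiftEdge(u, -1L, 0L) +
           shiftEdge(u, 0L, 1L) + shiftEdge(u, 0L, -1L)) / 4
    vb <- (shiftEdge(v, 1L, 0L) + shiftEdge(v, -1L, 0L) +
           shiftEdge(v, 0L, 1L) + shiftEdge(v, 0L, -1L)) / 4
    common <- (Ir * ub + Ic * vb + It) / denom
    u <- ub - Ir * common
    v <- vb - Ic * common
  }
  array(c(u, v), c(nrow(g1), ncol(g1), 2L))
}

#' Warp a label map along a flow field
#'
#' Nearest-neighbour label warping implemented as a forward splat: each
#' source pixel is moved by its flow vector rounded to the nearest integer
#' (half away from zero); colliding splats are resolved by class id (higher
#' class id on top) and target pixels receiving no source are background.
#' With exact integer flow this is the inverse-free equivalent of the
#' backward warp \eqn{m'_{t+1}(q) = m_t(q - \mathrm{flow}(q))} used for the
#' temporal-consistency metrics.
#'
#' @param mask integer label map at frame t.
#' @param flow numeric \code{H x W x 2} (drow, dcol) field mapping frame t to
#'   frame t+1.
#' @return the warped integer label map.
#' @examples
#' m <- matrix(0L, 4, 4); m[2, 2] <- 1L
#' fl <- array(0, c(4, 4, 2)); fl[, , 2] <- 1   # one column to the right
#' warpMask(m, fl)
#' @export
warpMask <- function(mask, flow) {
  H <- nrow(mask); W <- ncol(mask)
  stopShape(identical(dim(flow)[1:2], c(H, W)),
            "flow shape does not match the mask")
  stopShape(all(is.finite(flow)), "flow must be finite")
  r <- as.vector(row(mask)) + rhalf(as.vector(flow[, , 1]))
  cc <- as.vector(col(mask)) + rhalf(as.vector(flow[, , 2]))
  lab <- as.integer(mask)
  keep <- r >= 1 & r <= H & cc >= 1 & cc <= W & lab > 0L
  out <- matrix(0L, H, W)
  if (any(keep)) {
    r <- r[keep]; cc <- cc[keep]; lab <- lab[keep]
    ord <- order(lab)                  # higher class id splats last (on top)
    out[cbind(r[ord], cc[ord])] <- lab[ord]
  }
  out
}
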