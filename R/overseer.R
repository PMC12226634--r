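# Frame-wise overseer: oracle reference implementation, semantic mask
# rendering from detections, and class-set extraction.

#' Construct an oracle overseer
#'
#' The oracle derives detections from ground-truth label maps (one detection
#' per 8-connected component per class) and, when a [NoiseConfig] is given,
#' perturbs them once at construction so every [detect()] call is
#' deterministic. Any object implementing the [Overseer] contract can stand
#' in for it (adapter point for real detector backends).
#'
#' @param masks ground-truth [MaskSequence] (or a [SceneBundle], whose masks
#'   and schema are used).
#' @param schema the [LabelSchema]; ignored when a bundle is given.
#' @param noise optional [NoiseConfig].
#' @return an [OracleOverseer].
#' @export
OracleOverseer <- function(masks, schema = NULL, noise = NULL) {
  if (is(masks, "SceneBundle")) {
    schema <- masks@schema
    masks <- masks@masks
  }
  dets <- lapply(seq_len(nFrames(masks)), function(i)
    detectionsFromMask(masks@masks[[i]], schema,
                       frameId = masks@frameIds[i]))
  realization <- emptyRealization()
  if (!is.null(noise)) {
    dets <- perturbDetections(dets, noise, schema)
    realization <- attr(dets, "realization")
    attr(dets, "realization") <- NULL
  }
  new("OracleOverseer", masks = masks, schema = schema,
      dims = frameDims(masks), detections = dets,
      realization = realization)
}

#' @describeIn OracleOverseer detections for one frame; errors with
#'   \code{"unknown frame"} outside the bundle and checks the frame shape
#'   against the overseer's configured (H, W).
#' @param overseer,frame,frameId see [detect()].
#' @export
setMethod("detect", "OracleOverseer", function(overseer, frame, frameId) {
  i <- match(as.integer(frameId), overseer@masks@frameIds)
  if (is.na(i)) stop(sprintf("unknown frame %d", frameId), call. = FALSE)
  if (!is.null(frame) && !identical(dim(frame)[1:2],
                                    as.integer(overseer@dims)))
    stop("frame shape does not match the overseer's configured (H, W)",
         call. = FALSE)
  overseer@detections[[i]]
})

setMethod("show", "OracleOverseer", function(object) {
  cat(sprintf(
    "OracleOverseer: %d frames of %d x %d, %d injected noise events\n",
    nFrames(object@masks), object@dims[1], object@dims[2],
    nrow(object@realization)))
})

#' Render a semantic label map from detections
#'
#' Pixels covered by no instance mask (at threshold 0.5) are background;
#' pixels covered by several instances take the class of the highest-score
#' covering instance, ties resolved in favour of the lower detection index.
#'
#' @param dets a [DetectionSet].
#' @param schema optional [LabelSchema] for validation.
#' @return an integer label map.
#' @export
semanticMaskFromDetections <- function(dets, schema = NULL) {
  H <- dets@dims[1]; W <- dets@dims[2]
  out <- matrix(0L, H, W)
  n <- nDetections(dets)
  if (!n) return(out)
  # paint in increasing priority: ascending score, and among equal scores
  # descending index, so the highest score (lowest index on ties) wins
  ord <- order(dets@scores, -seq_len(n))
  for (i in ord) {
    fp <- dets@masks[[i]] >= 0.5
    out[fp] <- dets@classIds[i]
  }
  out
}

#' Set of classes present in a detection set
#'
#' Deduplicated class ids of all detections at or above the score threshold;
#' the buffer of the orchestrator tracks class presence, not instance counts.
#'
#' @param dets a [DetectionSet].
#' @param scoreThreshold minimum score (default 0.5).
#' @return sorted integer vector of class ids.
#' @export
classSet <- function(dets, scoreThreshold = 0.5) {
  sort(unique(dets@classIds[dets@scores >= scoreThreshold]))
}
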