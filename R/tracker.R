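# Reference video tracker: propagates the previous output label map along
# the inter-frame optical flow. By construction its output class set can
# never grow beyond the last prompt, reproducing the enter/leave failure mode
# of memory-based video segmentation that the overseer re-prompting corrects.

#' Construct a prompt set
#'
#' @param frameId 0-based prompt frame.
#' @param classIds integer vector of entity class ids.
#' @param masks list of full-frame binary masks, one per entity.
#' @param anchors list of \code{k x 2} (row, col) anchor matrices, 0-based;
#'   every anchor must lie inside its entity's mask.
#' @return a [PromptSet].
#' @export
PromptSet <- function(frameId, classIds, masks, anchors) {
  anchors <- lapply(anchors, function(a) {
    a <- rbind(a)
    storage.mode(a) <- "integer"
    a
  })
  new("PromptSet", frameId = as.integer(frameId),
      classIds = as.integer(classIds), masks = masks, anchors = anchors)
}

setMethod("show", "PromptSet", function(object) {
  cat(sprintf("PromptSet at frame %d: %d entities (classes %s)\n",
              object@frameId, length(object@classIds),
              classSetLabel(object@classIds)))
})

# label map of the prompted entities; later entities paint on top
renderPromptMask <- function(prompts, H, W) {
  out <- matrix(0L, H, W)
  for (i in seq_along(prompts@classIds))
    out[prompts@masks[[i]] != 0] <- prompts@classIds[i]
  out
}

#' Construct a flow-propagation tracker
#'
#' @param dims integer \code{c(H, W)} frame shape.
#' @param flowFields optional list of exact flow fields (element t maps frame
#'   t to t+1, 0-based), e.g. \code{bundle@flow}; when absent the tracker
#'   estimates flow from the frames passed to [promptTracker()] and
#'   [propagateTracker()].
#' @return a [FlowPropagationTracker].
#' @export
FlowPropagationTracker <- function(dims, flowFields = list()) {
  new("FlowPropagationTracker", dims = as.integer(dims),
      flowFields = flowFields, entities = NULL, outputs = list(),
      horizon = -1L, prevFrame = NULL)
}

setMethod("trackerHorizon", "FlowPropagationTracker",
          function(tracker) tracker@horizon)

setMethod("trackedMask", "FlowPropagationTracker",
          function(tracker, frameId) {
  if (frameId < 0L || frameId > tracker@horizon ||
      is.null(tracker@outputs[[frameId + 1L]]))
    stop(sprintf("no output for frame %d", frameId), call. = FALSE)
  tracker@outputs[[frameId + 1L]]
})

setMethod("trackedMasks", "FlowPropagationTracker", function(tracker) {
  if (tracker@horizon < 0L) stop("tracker not prompted", call. = FALSE)
  # a first prompt later than frame 0 leaves earlier slots empty
  start <- which(!vapply(tracker@outputs, is.null, logical(1)))[1]
  MaskSequence(tracker@outputs[start:(tracker@horizon + 1L)],
               (start:(tracker@horizon + 1L)) - 1L)
})

setMethod("show", "FlowPropagationTracker", function(object) {
  cat(sprintf(
    "FlowPropagationTracker %d x %d: horizon %d, %s flow, classes {%s}\n",
    object@dims[1], object@dims[2], object@horizon,
    if (length(object@flowFields)) "ground-truth" else "estimated",
    if (is.null(object@entities)) ""
    else classSetLabel(object@entities@classIds)))
})

#' @describeIn FlowPropagationTracker replace the tracked entity set; the
#'   output at the prompt frame equals the rendered prompt mask and the
#'   horizon moves there. Requires \code{prompts@frameId <= horizon + 1}.
#' @param tracker,prompts,frame see [promptTracker()].
#' @export
setMethod("promptTracker", "FlowPropagationTracker",
          function(tracker, prompts, frame = NULL) {
  if (length(prompts@classIds) < 1L)
    stop("nothing to track", call. = FALSE)
  if (tracker@horizon >= 0L && prompts@frameId > tracker@horizon + 1L)
    stop(sprintf("prompt frame %d beyond the tracker horizon %d",
                 prompts@frameId, tracker@horizon), call. = FALSE)
  for (m in prompts@masks)
    stopShape(identical(dim(m), as.integer(tracker@dims)),
              "prompt mask shape does not match the tracker")
  tracker@entities <- prompts
  tracker@outputs <- tracker@outputs[seq_len(prompts@frameId)]
  tracker@outputs[[prompts@frameId + 1L]] <-
    renderPromptMask(prompts, tracker@dims[1], tracker@dims[2])
  tracker@horizon <- prompts@frameId
  tracker@prevFrame <- frame
  tracker
})

#' @describeIn FlowPropagationTracker segment the frame at
#'   \code{horizon + 1} by warping the previous output along the inter-frame
#'   flow; classes never in the prompt cannot appear.
#' @export
setMethod("propagateTracker", "FlowPropagationTracker",
          function(tracker, frame = NULL) {
  if (is.null(tracker@entities) || tracker@horizon < 0L)
    stop("tracker not prompted", call. = FALSE)
  t <- tracker@horizon                       # flow t -> t+1
  if (length(tracker@flowFields)) {
    if (t + 1L > length(tracker@flowFields))
      stop(sprintf("no flow field for frames %d -> %d", t, t + 1L),
           call. = FALSE)
    fl <- tracker@flowFields[[t + 1L]]
  } else {
    if (is.null(tracker@prevFrame) || is.null(frame))
      stop(paste0("flow estimation needs the previous and current frames; ",
                  "pass frames to promptTracker/propagateTracker"),
           call. = FALSE)
    fl <- computeFlow(tracker@prevFrame, frame, method = "estimated")
  }
  tracker@outputs[[t + 2L]] <- warpMask(tracker@outputs[[t + 1L]], fl)
  tracker@horizon <- t + 1L
  tracker@prevFrame <- frame
  tracker
})

#' @describeIn FlowPropagationTracker discard memory beyond \code{frameId};
#'   a subsequent prompt at \code{frameId} is accepted and the continuation
#'   is independent of the discarded history.
#' @param frameId 0-based reset target.
#' @export
setMethod("resetTracker", "FlowPropagationTracker",
          function(tracker, frameId) {
  frameId <- as.integer(frameId)
  if (frameId < 0L) stop("invalid reset target", call. = FALSE)
  if (frameId > tracker@horizon)
    stop(sprintf("reset target %d beyond the horizon %d", frameId,
                 tracker@horizon), call. = FALSE)
  tracker@outputs <- tracker@outputs[seq_len(frameId + 1L)]
  tracker@horizon <- frameId
  tracker@prevFrame <- NULL   # stale for estimators; re-supplied at prompt
  tracker
})
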