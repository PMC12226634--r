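#' @include AllClasses.R
NULL

#' Number of frames in a sequence-like object
#' @param x a [FrameSequence], [MaskSequence] or [SceneBundle].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame ids of a sequence-like object
#' @param x a [FrameSequence] or [MaskSequence].
#' @return integer vector of 0-based frame ids.
#' @export
setGeneric("frameIds", function(x) standardGeneric("frameIds"))

#' Spatial dimensions (H, W)
#' @param x an object with a frame shape.
#' @return integer \code{c(H, W)}.
#' @export
setGeneric("frameDims", function(x) standardGeneric("frameDims"))

#' Extract a single frame / mask by frame id
#' @param x a [FrameSequence] or [MaskSequence].
#' @param frameId 0-based frame id.
#' @export
setGeneric("getFrame", function(x, frameId) standardGeneric("getFrame"))

#' @rdname getFrame
#' @export
setGeneric("getMask", function(x, frameId) standardGeneric("getMask"))

#' Run a frame-wise overseer on one frame
#'
#' The overseer contract: given a frame and its 0-based id, return the
#' [DetectionSet] for that frame.
#'
#' @param overseer an [Overseer] implementation.
#' @param frame an \code{H x W x 3} integer array.
#' @param frameId 0-based frame id.
#' @return a [DetectionSet].
#' @export
setGeneric("detect", function(overseer, frame, frameId)
  standardGeneric("detect"))

#' Prompt a tracker with a new entity set
#'
#' Replaces the tracked entities with those of \code{prompts}; the output
#' mask at the prompt frame equals the rendered prompt mask and the tracker
#' horizon moves to the prompt frame. The prompt frame must satisfy
#' \code{frameId <= horizon + 1}.
#'
#' @param tracker a [Tracker].
#' @param prompts a [PromptSet].
#' @param frame optional image at the prompt frame (required by trackers that
#'   estimate flow from pixels).
#' @return the updated tracker.
#' @export
setGeneric("promptTracker", function(tracker, prompts, frame = NULL)
  standardGeneric("promptTracker"))

#' Propagate a tracker by one frame
#'
#' Segments the frame at \code{horizon + 1} using the tracker's memory. The
#' reference [FlowPropagationTracker] warps its previous output mask along
#' the inter-frame flow; classes never prompted cannot appear.
#'
#' @param tracker a [Tracker] that has been prompted.
#' @param frame the image at \code{horizon + 1} (may be NULL for trackers
#'   running on supplied ground-truth flow).
#' @return the updated tracker; retrieve the new mask with [trackedMask()].
#' @export
setGeneric("propagateTracker", function(tracker, frame = NULL)
  standardGeneric("propagateTracker"))

#' Discard tracker memory beyond a frame
#'
#' After \code{resetTracker(tracker, k)} all memory for frames \code{> k} is
#' invalid, the horizon is \code{k} and a prompt at frame \code{k} is
#' accepted; the subsequent outputs are independent of the discarded history.
#'
#' @param tracker a [Tracker].
#' @param frameId 0-based reset target, \code{0 <= frameId <= horizon}.
#' @return the updated tracker.
#' @export
setGeneric("resetTracker", function(tracker, frameId)
  standardGeneric("resetTracker"))

#' Tracker output masks
#' @param tracker a [Tracker].
#' @return [trackedMasks()]: a [MaskSequence] of all outputs up to the
#'   horizon; [trackedMask()]: the single output label map at \code{frameId}.
#' @export
setGeneric("trackedMasks", function(tracker) standardGeneric("trackedMasks"))

#' @rdname trackedMasks
#' @param frameId 0-based frame id.
#' @export
setGeneric("trackedMask", function(tracker, frameId)
  standardGeneric("trackedMask"))

#' Tracker horizon
#' @param tracker a [Tracker].
#' @return last propagated 0-based frame id (-1 before any prompt).
#' @export
setGeneric("trackerHorizon", function(tracker)
  standardGeneric("trackerHorizon"))
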