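#' @import methods
NULL

# ---------------------------------------------------------------- label schema

#' Class schema for semantic label maps
#'
#' Maps contiguous integer class ids \code{0..C} to names, with id 0 always
#' the background. A palette colour per class accompanies the schema for
#' visualisation and is written to the schema sidecar file.
#'
#' @slot ids integer vector \code{0:C}.
#' @slot labels character vector of unique class names; \code{labels[1]} is
#'   the background name.
#' @slot palette integer matrix \code{(C+1) x 3} of RGB colours in 0..255,
#'   one row per class id.
#' @export
setClass("LabelSchema",
  representation(ids = "integer", labels = "character", palette = "matrix"))

setValidity("LabelSchema", function(object) {
  C <- length(object@ids) - 1L
  if (C < 1L) return("schema needs at least one non-background class (C >= 1)")
  if (!identical(object@ids, 0:C)) return("class ids must be contiguous 0..C")
  if (length(object@labels) != C + 1L) return("one name per class id required")
  if (anyDuplicated(object@labels)) return("class names must be unique")
  if (!is.numeric(object@palette) || !identical(dim(object@palette),
      c(C + 1L, 3L)))
    return("palette must be a (C+1) x 3 matrix")
  if (any(object@palette < 0 | object@palette > 255))
    return("palette entries must be within 0..255")
  TRUE
})

# ------------------------------------------------------------- frame sequences

#' Ordered RGB frame sequence of a video
#'
#' Holds frames \eqn{v_0, \dots, v_{T-1}} as integer arrays of shape
#' \code{H x W x 3} with intensities 0..255. Frame ids are 0-based and
#' strictly increasing; pixel coordinates are (row, col) with origin at the
#' top-left.
#'
#' @slot frames list of \code{H x W x 3} integer arrays.
#' @slot frameIds integer vector of 0-based frame ids.
#' @export
setClass("FrameSequence",
  representation(frames = "list", frameIds = "integer"))

setValidity("FrameSequence", function(object) {
  if (length(object@frames) < 1L) return("at least one frame required")
  if (length(object@frames) != length(object@frameIds))
    return("one frame id per frame required")
  if (any(diff(object@frameIds) <= 0L))
    return("frame ids must be strictly increasing")
  d0 <- dim(object@frames[[1]])
  for (i in seq_along(object@frames)) {
    f <- object@frames[[i]]
    if (length(dim(f)) != 3L || dim(f)[3] != 3L)
      return(sprintf("frame %d is not an H x W x 3 array",
                     object@frameIds[i]))
    if (!identical(dim(f)[1:2], d0[1:2]))
      return(sprintf("shape mismatch at frame %d", object@frameIds[i]))
    if (min(f) < 0 || max(f) > 255)
      return(sprintf("frame %d has intensities outside 0..255",
                     object@frameIds[i]))
  }
  TRUE
})

#' Per-frame semantic label maps
#'
#' Label maps aligned with a [FrameSequence]; values are class ids of a
#' [LabelSchema] (0 = background).
#'
#' @slot masks list of integer \code{H x W} matrices.
#' @slot frameIds integer vector of 0-based frame ids.
#' @export
setClass("MaskSequence",
  representation(masks = "list", frameIds = "integer"))

setValidity("MaskSequence", function(object) {
  if (length(object@masks) < 1L) return("at least one mask required")
  if (length(object@masks) != length(object@frameIds))
    return("one frame id per mask required")
  if (any(diff(object@frameIds) <= 0L))
    return("frame ids must be strictly increasing")
  d0 <- dim(object@masks[[1]])
  for (i in seq_along(object@masks)) {
    m <- object@masks[[i]]
    if (!is.matrix(m)) return("masks must be matrices")
    if (!identical(dim(m), d0))
      return(sprintf("shape mismatch at frame %d", object@frameIds[i]))
    if (min(m) < 0) return("negative label encountered")
  }
  TRUE
})

# ------------------------------------------------------------------ detections

#' Frame-wise detections of an overseer
#'
#' Per-frame output of a detection overseer: class ids, confidence scores,
#' normalised bounding boxes and full-frame instance masks. Boxes are
#' \code{(x_min, y_min, x_max, y_max)} in \eqn{[0,1]^4}, half-open, with x
#' along columns and y along rows. Instance masks are full-frame matrices in
#' \eqn{[0,1]} (thresholded at 0.5 where a binary footprint is needed).
#'
#' @slot frameId 0-based frame id.
#' @slot classIds integer vector of class ids (one per detection).
#' @slot scores numeric vector of confidences in \eqn{[0,1]}.
#' @slot boxes numeric \code{n x 4} matrix of normalised boxes.
#' @slot masks list of \code{H x W} instance masks.
#' @slot dims integer \code{c(H, W)} of the frame the detections refer to.
#' @export
setClass("DetectionSet",
  representation(frameId = "integer", classIds = "integer",
                 scores = "numeric", boxes = "matrix", masks = "list",
                 dims = "integer"))

setValidity("DetectionSet", function(object) {
  n <- length(object@classIds)
  if (length(object@scores) != n || nrow(object@boxes) != n ||
      length(object@masks) != n)
    return("classIds, scores, boxes and masks must have equal length")
  if (length(object@dims) != 2L) return("dims must be c(H, W)")
  if (n == 0L) return(TRUE)
  if (ncol(object@boxes) != 4L) return("boxes must be n x 4")
  if (any(object@classIds < 1L)) return("detections cannot be background")
  if (any(object@scores < 0 | object@scores > 1))
    return("scores must be within [0, 1]")
  if (any(object@boxes < 0 | object@boxes > 1))
    return("boxes must be normalised to [0, 1]")
  if (any(object@boxes[, 1] >= object@boxes[, 3]) ||
      any(object@boxes[, 2] >= object@boxes[, 4]))
    return("boxes must satisfy x_min < x_max and y_min < y_max")
  for (m in object@masks) {
    if (!identical(dim(m), object@dims))
      return("instance masks must share the frame shape")
    if (min(m) < 0 || max(m) > 1)
      return("instance masks must be within [0, 1]")
  }
  TRUE
})

# --------------------------------------------------------------- scene configs

#' Specification of one synthetic scene object
#'
#' A moving (or static) shape with a class id, an entry/exit frame window and
#' an integer-valued velocity. Supported shapes: \code{"disk"} (radius),
#' \code{"rectangle"} (height, width) and \code{"capsule"} (radius, length,
#' angle in degrees). \code{center} is the (row, col) position, 0-based, of
#' the shape centre at its entry frame.
#'
#' @slot classId integer class id (>= 1).
#' @slot shape one of \code{"disk"}, \code{"rectangle"}, \code{"capsule"}.
#' @slot size named numeric vector of shape parameters in pixels.
#' @slot center numeric length-2 (row, col) at the entry frame, 0-based.
#' @slot velocity numeric length-2 (drow, dcol) pixels per frame.
#' @slot entryFrame,exitFrame 0-based frame window \code{[entry, exit)} during
#'   which the object is present.
#' @export
setClass("ObjectSpec",
  representation(classId = "integer", shape = "character", size = "numeric",
                 center = "numeric", velocity = "numeric",
                 entryFrame = "integer", exitFrame = "integer"))

setValidity("ObjectSpec", function(object) {
  if (!object@shape %in% c("disk", "rectangle", "capsule"))
    return("shape must be disk, rectangle or capsule")
  if (object@classId < 1L) return("object class id must be >= 1")
  if (length(object@center) != 2L || length(object@velocity) != 2L)
    return("center and velocity must have length 2")
  if (object@entryFrame < 0L || object@exitFrame <= object@entryFrame)
    return("entry frame must satisfy 0 <= entry < exit")
  TRUE
})

#' Synthetic scene configuration
#'
#' Scene geometry, label schema, object list (painted in list order, later
#' objects on top), static background regions and the seeds controlling the
#' procedural textures and pixel noise.
#'
#' @slot height,width frame size in pixels.
#' @slot nFrames number of frames T (>= 2).
#' @slot schema the [LabelSchema] of the scene.
#' @slot objects list of [ObjectSpec] for moving objects.
#' @slot backgroundRegions list of [ObjectSpec] painted as static anatomy
#'   regions below all objects (velocity must be zero).
#' @slot textureSeed,noiseSeed integer seeds for textures and pixel noise.
#' @export
setClass("SceneConfig",
  representation(height = "integer", width = "integer", nFrames = "integer",
                 schema = "LabelSchema", objects = "list",
                 backgroundRegions = "list",
                 textureSeed = "integer", noiseSeed = "integer"))

setValidity("SceneConfig", function(object) {
  if (object@nFrames < 2L) return("a scene needs at least two frames")
  if (object@height < 4L || object@width < 4L)
    return("scene must be at least 4 x 4 pixels")
  C <- length(object@schema@ids) - 1L
  for (o in c(object@objects, object@backgroundRegions)) {
    if (!is(o, "ObjectSpec")) return("objects must be ObjectSpec instances")
    if (o@classId > C)
      return(sprintf("object class %d outside schema (C = %d)", o@classId, C))
    if (o@exitFrame > object@nFrames)
      return("object exit frame beyond the end of the scene")
  }
  for (o in object@backgroundRegions)
    if (any(o@velocity != 0))
      return("background regions must be static (zero velocity)")
  TRUE
})

#' Detection noise model
#'
#' Stochastic perturbation of oracle detections emulating an imperfect
#' frame-wise detector: whole-detection misses, spurious short-lived
#' detections ("blips") of random classes, morphological boundary jitter and
#' additive score noise. All draws are governed by \code{seed}; a realisation
#' log of the injected events is attached to the perturbed output.
#'
#' @slot missProb per-detection per-frame probability of dropping a detection.
#' @slot spuriousProb per-class per-frame probability that a spurious blip
#'   starts at that frame.
#' @slot spuriousDuration integer length-2 inclusive range of blip durations
#'   in frames (blips are truncated at the end of the video).
#' @slot jitterRange integer length-2 range of dilation/erosion radii applied
#'   to instance masks (0,0 disables jitter).
#' @slot scoreSd standard deviation of additive Gaussian score noise.
#' @slot seed integer RNG seed.
#' @export
setClass("NoiseConfig",
  representation(missProb = "numeric", spuriousProb = "numeric",
                 spuriousDuration = "integer", jitterRange = "integer",
                 scoreSd = "numeric", seed = "integer"))

setValidity("NoiseConfig", function(object) {
  if (object@missProb < 0 || object@missProb > 1 ||
      object@spuriousProb < 0 || object@spuriousProb > 1)
    return("probabilities must be within [0, 1]")
  if (length(object@spuriousDuration) != 2L ||
      any(object@spuriousDuration < 1L) ||
      object@spuriousDuration[1] > object@spuriousDuration[2])
    return("spurious durations must be an increasing range of >= 1 frames")
  if (length(object@jitterRange) != 2L || any(object@jitterRange < 0L) ||
      object@jitterRange[1] > object@jitterRange[2])
    return("jitter range must be a non-negative increasing range")
  if (object@scoreSd < 0) return("score noise sd must be non-negative")
  TRUE
})

#' Generated synthetic scene with full ground truth
#'
#' Output of [generateScene()]: rendered frames, ground-truth label maps,
#' exact ground-truth flow fields (list of \code{H x W x 2} arrays, element t
#' mapping frame t to t+1), per-frame ground-truth detections and the
#' entry/exit event log.
#'
#' @slot frames a [FrameSequence].
#' @slot masks a [MaskSequence] of ground-truth label maps.
#' @slot flow list of \code{T-1} flow arrays \code{H x W x 2} (drow, dcol).
#' @slot detections list of \code{T} [DetectionSet] objects.
#' @slot events data.frame with columns object_id, class_id, entry, exit.
#' @slot schema the scene's [LabelSchema].
#' @slot config the generating [SceneConfig].
#' @export
setClass("SceneBundle",
  representation(frames = "FrameSequence", masks = "MaskSequence",
                 flow = "list", detections = "list", events = "data.frame",
                 schema = "LabelSchema", config = "SceneConfig"))

# ----------------------------------------------------------- tracker & prompts

#' Prompt for a video tracker
#'
#' The entities handed to a tracker at a prompt frame: one entity per class,
#' each with a full-frame binary instance mask and >= 1 positive anchor
#' points lying inside the mask. Anchor coordinates are 0-based (row, col).
#'
#' @slot frameId 0-based frame the prompt refers to.
#' @slot classIds integer vector of entity class ids.
#' @slot masks list of logical/0-1 matrices, one per entity.
#' @slot anchors list of integer \code{k x 2} matrices of (row, col) anchors.
#' @export
setClass("PromptSet",
  representation(frameId = "integer", classIds = "integer", masks = "list",
                 anchors = "list"))

setValidity("PromptSet", function(object) {
  n <- length(object@classIds)
  if (n < 1L) return("nothing to track: a prompt needs at least one entity")
  if (length(object@masks) != n || length(object@anchors) != n)
    return("one mask and one anchor matrix per entity required")
  for (i in seq_len(n)) {
    m <- object@masks[[i]]
    a <- object@anchors[[i]]
    if (!is.matrix(a) || ncol(a) != 2L || nrow(a) < 1L)
      return("anchors must be k x 2 (row, col) matrices with k >= 1")
    if (any(a < 0) || any(a[, 1] >= nrow(m)) || any(a[, 2] >= ncol(m)))
      return("anchor point outside the frame")
    if (any(m[cbind(a[, 1] + 1L, a[, 2] + 1L)] == 0))
      return("anchor point outside its mask")
    if (!any(m != 0)) return("entity mask is empty")
  }
  TRUE
})

#' Video tracker contract
#'
#' Virtual parent of tracker implementations. A tracker is prompted with a
#' [PromptSet] ([promptTracker()]), propagates one frame at a time
#' ([propagateTracker()]) and can discard memory beyond a frame
#' ([resetTracker()]) so a corrected prompt can be applied in the past.
#' Tracker state is value-semantic: every operation returns the updated
#' tracker.
#'
#' @export
setClass("Tracker", representation("VIRTUAL"))

#' Reference tracker propagating masks along optical flow
#'
#' Reproduces the characteristic failure mode of memory-based video
#' segmentation: the output class set can never grow beyond the classes in
#' the last prompt, so entities entering after the prompt frame are missed
#' until a re-prompt. Propagation warps the previous output label map by the
#' flow between the previous and current frame (exact ground-truth flow when
#' supplied, a dense Horn-Schunck estimate otherwise).
#'
#' @slot dims integer \code{c(H, W)}.
#' @slot flowFields list of ground-truth flow arrays (element t maps frame t
#'   to t+1) or empty to use the estimator.
#' @slot entities the active [PromptSet] (or NULL before the first prompt).
#' @slot outputs list of output label maps for frames \code{0..horizon}.
#' @slot horizon last propagated 0-based frame id (-1 before any prompt).
#' @slot prevFrame the image at \code{horizon} (needed by the estimator).
#' @export
setClass("FlowPropagationTracker", contains = "Tracker",
  representation(dims = "integer", flowFields = "list", entities = "ANY",
                 outputs = "list", horizon = "integer", prevFrame = "ANY"))

# ------------------------------------------------------------------- overseers

#' Frame-wise overseer contract
#'
#' Virtual parent of overseer implementations; an overseer maps a frame to a
#' [DetectionSet] via [detect()]. Real detector backends (Mask R-CNN class
#' models) plug in by subclassing and implementing \code{detect}.
#'
#' @export
setClass("Overseer", representation("VIRTUAL"))

#' Oracle overseer backed by ground-truth masks plus a noise model
#'
#' Derives detections from ground-truth label maps (one detection per
#' 8-connected component per non-background class) and optionally perturbs
#' them with a [NoiseConfig]. The perturbation is realised once at
#' construction, so repeated [detect()] calls are deterministic.
#'
#' @slot masks ground-truth [MaskSequence].
#' @slot schema the [LabelSchema].
#' @slot dims integer \code{c(H, W)}.
#' @slot detections list of (possibly perturbed) [DetectionSet] per frame.
#' @slot realization data.frame log of injected noise events.
#' @export
setClass("OracleOverseer", contains = "Overseer",
  representation(masks = "MaskSequence", schema = "LabelSchema",
                 dims = "integer", detections = "list",
                 realization = "data.frame"))

# ------------------------------------------------------------------ orchestral

#' Class-constellation buffer
#'
#' Per-frame record of the class sets reported by the overseer since the last
#' prompt, together with the reference set (the classes active at that
#' prompt). Consumed by [detectPersistentChange()].
#'
#' @slot frameIds integer vector of buffered 0-based frame ids (contiguous).
#' @slot sets list of integer class-id vectors, one per buffered frame.
#' @slot referenceSet integer vector: class set of the last prompt.
#' @export
setClass("ClassBuffer",
  representation(frameIds = "integer", sets = "list",
                 referenceSet = "integer"))

setValidity("ClassBuffer", function(object) {
  if (length(object@frameIds) != length(object@sets))
    return("one class set per buffered frame required")
  if (length(object@frameIds) > 1L && any(diff(object@frameIds) != 1L))
    return("buffered frames must be contiguous")
  TRUE
})

#' Configuration of the re-prompting orchestration
#'
#' @slot nT persistence threshold in frames a constellation discrepancy must
#'   last before triggering a re-prompt (default 4).
#' @slot scoreThreshold minimum detection score for a class to count as
#'   present (default 0.5).
#' @slot anchorsPerComponent number of anchor points sampled per connected
#'   component of each prompted class (default 1).
#' @slot seed integer seed reserved for stochastic tracker/overseer backends;
#'   the shipped reference implementations are deterministic.
#' @export
setClass("RepromptConfig",
  representation(nT = "integer", scoreThreshold = "numeric",
                 anchorsPerComponent = "integer", seed = "integer"))

setValidity("RepromptConfig", function(object) {
  if (object@nT < 1L) return("persistence threshold nT must be >= 1")
  if (object@anchorsPerComponent < 1L)
    return("anchorsPerComponent must be >= 1")
  if (object@scoreThreshold < 0 || object@scoreThreshold > 1)
    return("scoreThreshold must be within [0, 1]")
  TRUE
})

#' Result of an orchestrated video segmentation run
#'
#' @slot masks the output [MaskSequence] covering all frames.
#' @slot log data.frame of re-prompt records (trigger_frame, reprompt_frame,
#'   old_classes, new_classes as comma-separated id strings).
#' @slot promptFrame 0-based frame of the initial prompt (NA if the overseer
#'   never reported any entity).
#' @slot notes character vector of warnings (deferred prompts, dropped
#'   classes).
#' @export
setClass("RepromptRun",
  representation(masks = "MaskSequence", log = "data.frame",
                 promptFrame = "integer", notes = "character"))

# --------------------------------------------------------------------- reports

#' Temporal-consistency report
#'
#' Per frame pair (t, t+1): macro Dice/IoU of the flow-warped previous mask
#' against the next mask (warped Dice/IoU), the contour distance and the
#' plain inter-frame macro IoU; plus their sequence means (contour-distance
#' pairs without any contour are excluded from the mean).
#'
#' @slot perPair data.frame with columns pair, dice_of, iou_of, cd_t, iou_t.
#' @slot means named numeric vector of the four sequence means.
#' @export
setClass("ConsistencyReport",
  representation(perPair = "data.frame", means = "numeric"))

#' Per-frame detection and segmentation report
#'
#' @slot classF1 pooled F1 of class predictions at 50\% box IoU.
#' @slot bbIoU mean box IoU over true-positive pairs.
#' @slot maskDice mean instance-mask Dice over true positives with mask IoU
#'   >= 0.5.
#' @slot semanticDice mean per-frame macro Dice of rendered semantic masks.
#' @slot counts named numeric vector (tp, fp, fn).
#' @export
setClass("DetectionReport",
  representation(classF1 = "numeric", bbIoU = "numeric", maskDice = "numeric",
                 semanticDice = "numeric", counts = "numeric"))

#' Multi-task detection loss breakdown
#'
#' The three averaged loss terms of the detection overseer objective (class
#' cross-entropy, smooth-L1 box regression, per-pixel mask cross-entropy) and
#' their sum.
#'
#' @slot cls,box,mask,total non-negative scalars with
#'   \code{total = cls + box + mask}.
#' @export
setClass("LossBreakdown",
  representation(cls = "numeric", box = "numeric", mask = "numeric",
                 total = "numeric"))
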