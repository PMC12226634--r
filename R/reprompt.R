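# Re-prompting orchestration: monitor overseer class sets in a buffer,
# detect persistent scene-constellation changes, back-track, sample anchor
# prompts from the overseer mask, re-prompt the tracker and emit the full
# corrected mask sequence with a re-prompt log.

#' Construct an orchestration configuration
#'
#' @param nT persistence threshold in frames (default 4): a constellation
#'   discrepancy must hold for nT + 1 consecutive frames before a re-prompt
#'   is triggered, suppressing short detector blips.
#' @param scoreThreshold minimum detection score for class presence.
#' @param anchorsPerComponent anchor points per connected component.
#' @param seed reserved for stochastic backends.
#' @return a [RepromptConfig].
#' @export
RepromptConfig <- function(nT = 4L, scoreThreshold = 0.5,
                           anchorsPerComponent = 1L, seed = 1L) {
  new("RepromptConfig", nT = as.integer(nT),
      scoreThreshold = scoreThreshold,
      anchorsPerComponent = as.integer(anchorsPerComponent),
      seed = as.integer(seed))
}

#' Construct a class buffer
#'
#' @param referenceSet integer class set active at the last prompt.
#' @param frameIds,sets buffered frames and their class sets.
#' @return a [ClassBuffer].
#' @export
ClassBuffer <- function(referenceSet = integer(0), frameIds = integer(0),
                        sets = list()) {
  new("ClassBuffer", frameIds = as.integer(frameIds), sets = sets,
      referenceSet = sort(unique(as.integer(referenceSet))))
}

#' Append a frame's class set to a buffer
#' @param buffer a [ClassBuffer].
#' @param frameId 0-based frame id (must extend the buffer contiguously).
#' @param set integer class set reported for that frame.
#' @export
bufferAppend <- function(buffer, frameId, set) {
  buffer@frameIds <- c(buffer@frameIds, as.integer(frameId))
  buffer@sets <- c(buffer@sets, list(sort(unique(as.integer(set)))))
  validObject(buffer)
  buffer
}

setMethod("show", "ClassBuffer", function(object) {
  cat(sprintf("ClassBuffer: %d frames buffered, reference {%s}\n",
              length(object@frameIds), classSetLabel(object@referenceSet)))
})

#' Detect a persistent class-constellation change
#'
#' Triggers iff the buffered class set differs from the reference set on
#' every frame of the window \code{[currentFrame - nT, currentFrame]}, i.e.
#' after nT + 1 consecutive discrepant frames. The discrepant sets need not
#' be identical across the window, so drifting spurious labels still count
#' as one persistent change. Returns \code{NULL} or a list with the trigger
#' frame \code{tPrime = currentFrame} and the back-track frame
#' \code{backtrack = currentFrame - nT} (the first frame of the run).
#'
#' @param buffer a [ClassBuffer].
#' @param nT persistence threshold.
#' @param currentFrame 0-based frame to test.
#' @return \code{NULL} or \code{list(tPrime, backtrack)}.
#' @export
detectPersistentChange <- function(buffer, nT, currentFrame) {
  window <- (currentFrame - nT):currentFrame
  idx <- match(window, buffer@frameIds)
  if (anyNA(idx)) return(NULL)
  ref <- buffer@referenceSet
  for (i in idx)
    if (identical(buffer@sets[[i]], ref)) return(NULL)
  list(tPrime = currentFrame, backtrack = currentFrame - nT)
}

#' Sample anchor points from a semantic mask
#'
#' For every 8-connected component of every requested class the first anchor
#' is the most interior pixel (argmax of the Euclidean distance transform,
#' with the frame border counting as boundary), ties broken in row-major
#' order; additional anchors (k > 1) are further local maxima of the
#' distance transform in decreasing depth order. Deterministic.
#'
#' @param mask integer label map.
#' @param classes integer class ids to sample for (default: all
#'   non-background classes present).
#' @param k anchors per component (components with fewer distinct local
#'   maxima yield fewer anchors).
#' @return data.frame with columns class_id, component, row, col (0-based
#'   pixel coordinates).
#' @export
sampleAnchorPoints <- function(mask, classes = NULL, k = 1L) {
  present <- sort(unique(as.integer(mask[mask > 0L])))
  if (is.null(classes)) classes <- present
  out <- data.frame(class_id = integer(0), component = integer(0),
                    row = integer(0), col = integer(0))
  for (cls in sort(unique(as.integer(classes)))) {
    if (!cls %in% present)
      stop(sprintf("empty class %d", cls), call. = FALSE)
    lab <- labelComponents8(mask == cls)
    for (comp in seq_len(max(lab))) {
      cm <- lab == comp
      d <- interiorDistance(cm)
      # global argmax, row-major tie-break
      cand <- which(cm & d >= max(d[cm]) - 1e-12, arr.ind = TRUE)
      best <- cand[orderRowMajor(cand[, 1], cand[, 2])[1], , drop = FALSE]
      pts <- best
      if (k > 1L) {
        lm <- localMaxima8(d, cm)
        depth <- d[lm]
        ord <- order(-depth, lm[, 1], lm[, 2])
        lm <- lm[ord, , drop = FALSE]
        dup <- lm[, 1] == best[1, 1] & lm[, 2] == best[1, 2]
        lm <- lm[!dup, , drop = FALSE]
        extra <- utils::head(seq_len(nrow(lm)), k - 1L)
        pts <- rbind(pts, lm[extra, , drop = FALSE])
      }
      out <- rbind(out, data.frame(class_id = cls, component = comp,
                                   row = pts[, 1] - 1L,
                                   col = pts[, 2] - 1L))
    }
  }
  out
}

# Build the prompt at `frameId` from overseer detections: semantic mask,
# per-class entity masks and per-component anchors. Classes whose rendered
# mask is empty (jitter erased the footprint) are dropped with a note.
buildPrompt <- function(dets, frameId, config) {
  sem <- semanticMaskFromDetections(dets)
  classes <- classSet(dets, config@scoreThreshold)
  notes <- character(0)
  keep <- logical(length(classes))
  masks <- list(); anchors <- list()
  for (i in seq_along(classes)) {
    m <- sem == classes[i]
    if (!any(m)) {
      notes <- c(notes, sprintf(
        "frame %d: class %d dropped from prompt (empty mask)", frameId,
        classes[i]))
      next
    }
    a <- sampleAnchorPoints(sem, classes = classes[i],
                            k = config@anchorsPerComponent)
    keep[i] <- TRUE
    masks <- c(masks, list(m))
    anchors <- c(anchors, list(as.matrix(a[, c("row", "col")])))
  }
  if (!any(keep))
    return(list(prompt = NULL, classes = integer(0), notes = notes))
  list(prompt = PromptSet(frameId, classes[keep], masks, anchors),
       classes = classes[keep], notes = notes)
}

emptyRepromptLog <- function()
  data.frame(trigger_frame = integer(0), reprompt_frame = integer(0),
             old_classes = character(0), new_classes = character(0))

#' Orchestrated video segmentation with overseer-triggered re-prompting
#'
#' Prompts the tracker from the overseer's mask at the first frame with
#' detections, then propagates frame by frame while buffering the overseer's
#' class set. When the constellation differs from the reference set for
#' nT + 1 consecutive frames (trigger frame t'), the tracker memory is reset
#' to t' - nT - 1, a fresh prompt is built from the overseer mask at
#' t' - nT (the first frame of the change) and frames t' - nT .. t' are
#' re-segmented, overwriting the earlier outputs; the reference set becomes
#' the newly prompted class set and monitoring continues to the end of the
#' video.
#'
#' @param frames a [FrameSequence].
#' @param overseer an [Overseer].
#' @param tracker an unprompted [Tracker].
#' @param schema the [LabelSchema].
#' @param config a [RepromptConfig].
#' @return a [RepromptRun] with the complete output [MaskSequence] (always T
#'   frames), the re-prompt log and any notes.
#' @export
runReprompt <- function(frames, overseer, tracker, schema,
                        config = RepromptConfig()) {
  T <- nFrames(frames)
  dims <- frameDims(frames)
  outputs <- vector("list", T)
  notes <- character(0)
  log <- emptyRepromptLog()

  # initial prompt at the first frame with detections
  p <- NA_integer_
  built <- NULL
  for (t in seq_len(T) - 1L) {
    dets <- detect(overseer, getFrame(frames, t), t)
    built <- buildPrompt(dets, t, config)
    notes <- c(notes, built$notes)
    if (!is.null(built$prompt)) {
      p <- t
      break
    }
    outputs[[t + 1L]] <- matrix(0L, dims[1], dims[2])
  }
  if (is.na(p)) {
    notes <- c(notes, "overseer reported no entities in any frame")
    return(new("RepromptRun", masks = MaskSequence(outputs),
               log = log, promptFrame = NA_integer_, notes = notes))
  }
  if (p > 0L)
    notes <- c(notes, sprintf("initial prompt deferred to frame %d", p))
  tracker <- promptTracker(tracker, built$prompt, getFrame(frames, p))
  outputs[[p + 1L]] <- trackedMask(tracker, p)
  buffer <- ClassBuffer(referenceSet = built$classes)

  t <- p + 1L
  while (t <= T - 1L) {
    tracker <- propagateTracker(tracker, getFrame(frames, t))
    outputs[[t + 1L]] <- trackedMask(tracker, t)
    dets <- detect(overseer, getFrame(frames, t), t)
    buffer <- bufferAppend(buffer, t, classSet(dets, config@scoreThreshold))
    trig <- detectPersistentChange(buffer, config@nT, t)
    if (!is.null(trig)) {
      b <- trig$backtrack
      detsB <- detect(overseer, getFrame(frames, b), b)
      builtB <- buildPrompt(detsB, b, config)
      notes <- c(notes, builtB$notes)
      if (is.null(builtB$prompt)) {
        # overseer mask vanished entirely at the back-track frame; keep the
        # current prompt and clear the run so monitoring can restart
        notes <- c(notes, sprintf(
          "frame %d: re-prompt skipped (no usable overseer mask)", b))
        buffer@frameIds <- integer(0)
        buffer@sets <- list()
      } else {
        tracker <- resetTracker(tracker, b - 1L)
        tracker <- promptTracker(tracker, builtB$prompt, getFrame(frames, b))
        outputs[[b + 1L]] <- trackedMask(tracker, b)
        for (s in (b + 1L):t) {
          tracker <- propagateTracker(tracker, getFrame(frames, s))
          outputs[[s + 1L]] <- trackedMask(tracker, s)
        }
        log <- rbind(log, data.frame(
          trigger_frame = trig$tPrime, reprompt_frame = b,
          old_classes = classSetLabel(buffer@referenceSet),
          new_classes = classSetLabel(builtB$classes)))
        buffer <- ClassBuffer(referenceSet = builtB$classes)
      }
    }
    t <- t + 1L
  }
  new("RepromptRun", masks = MaskSequence(outputs), log = log,
      promptFrame = p, notes = notes)
}

setMethod("show", "RepromptRun", function(object) {
  cat(sprintf(
    "RepromptRun: %d frames, initial prompt at %s, %d re-prompt(s)\n",
    nFrames(object@masks),
    if (is.na(object@promptFrame)) "none" else object@promptFrame,
    nrow(object@log)))
  if (nrow(object@log))
    for (i in seq_len(nrow(object@log)))
      cat(sprintf("  trigger %d -> re-prompt %d ({%s} -> {%s})\n",
                  object@log$trigger_frame[i], object@log$reprompt_frame[i],
                  object@log$old_classes[i], object@log$new_classes[i]))
})

#' Write / read a re-prompt log
#'
#' Line format: \code{t_prime t_reprompt old_set new_set} with class sets as
#' comma-separated ids (or \code{-} for the empty set).
#'
#' @param log the \code{log} data.frame of a [RepromptRun].
#' @param path file path.
#' @export
writeRepromptLog <- function(log, path) {
  enc <- function(s) ifelse(nzchar(s), s, "-")
  lines <- c("# t_prime t_reprompt old_set new_set",
             sprintf("%d %d %s %s", log$trigger_frame, log$reprompt_frame,
                     enc(log$old_classes), enc(log$new_classes)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeRepromptLog
#' @export
readRepromptLog <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(emptyRepromptLog())
  parts <- strsplit(lines, " +")
  dec <- function(s) ifelse(s == "-", "", s)
  data.frame(
    trigger_frame = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    reprompt_frame = vapply(parts, function(p) as.integer(p[2]), integer(1)),
    old_classes = vapply(parts, function(p) dec(p[3]), character(1)),
    new_classes = vapply(parts, function(p) dec(p[4]), character(1)))
}
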