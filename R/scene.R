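# Synthetic scene generator: textured background "anatomy" regions plus
# moving "instrument" shapes that enter and leave at scripted frames, with
# exact ground-truth masks, flow, detections and an event log.

#' Construct an object specification
#'
#' @param classId class id (>= 1).
#' @param shape \code{"disk"}, \code{"rectangle"} or \code{"capsule"}.
#' @param center (row, col) of the shape centre at the entry frame, 0-based.
#' @param velocity (drow, dcol) pixels per frame; integer values keep the
#'   ground-truth flow exact under nearest-neighbour warping.
#' @param entryFrame,exitFrame 0-based presence window \code{[entry, exit)}.
#' @param radius disk/capsule radius in pixels.
#' @param height,width rectangle extent in pixels.
#' @param length capsule axis length in pixels.
#' @param angle capsule axis angle in degrees (0 = along columns).
#' @return an [ObjectSpec].
#' @export
ObjectSpec <- function(classId, shape = c("disk", "rectangle", "capsule"),
                       center, velocity = c(0, 0), entryFrame = 0L,
                       exitFrame, radius = NULL, height = NULL,
                       width = NULL, length = NULL, angle = 0) {
  shape <- match.arg(shape)
  size <- switch(shape,
    disk = c(radius = as.numeric(radius)),
    rectangle = c(height = as.numeric(height), width = as.numeric(width)),
    capsule = c(radius = as.numeric(radius), length = as.numeric(length),
                angle = as.numeric(angle)))
  new("ObjectSpec", classId = as.integer(classId), shape = shape,
      size = size, center = as.numeric(center),
      velocity = as.numeric(velocity), entryFrame = as.integer(entryFrame),
      exitFrame = as.integer(exitFrame))
}

#' Construct a scene configuration
#'
#' @param height,width frame size in pixels.
#' @param nFrames number of frames T.
#' @param schema the [LabelSchema].
#' @param objects list of moving [ObjectSpec] (painted in list order, later
#'   objects on top).
#' @param backgroundRegions list of static [ObjectSpec] anatomy regions
#'   painted below all objects.
#' @param textureSeed,noiseSeed seeds for procedural texture and pixel noise.
#' @return a [SceneConfig].
#' @export
SceneConfig <- function(height, width, nFrames, schema, objects = list(),
                        backgroundRegions = list(), textureSeed = 1L,
                        noiseSeed = 2L) {
  new("SceneConfig", height = as.integer(height), width = as.integer(width),
      nFrames = as.integer(nFrames), schema = schema, objects = objects,
      backgroundRegions = backgroundRegions,
      textureSeed = as.integer(textureSeed),
      noiseSeed = as.integer(noiseSeed))
}

# (dr, dc) integer offsets of the shape's pixels relative to its centre
shapeOffsets <- function(spec) {
  s <- spec@size
  ext <- switch(spec@shape,
    disk = ceiling(s[["radius"]]),
    rectangle = ceiling(max(s[["height"]], s[["width"]]) / 2) + 1,
    capsule = ceiling(s[["radius"]] + s[["length"]] / 2) + 1)
  g <- expand.grid(dr = -ext:ext, dc = -ext:ext)
  keep <- switch(spec@shape,
    disk = g$dr^2 + g$dc^2 <= s[["radius"]]^2,
    rectangle = {
      h <- s[["height"]]; w <- s[["width"]]
      r0 <- -floor((h - 1) / 2); c0 <- -floor((w - 1) / 2)
      g$dr >= r0 & g$dr < r0 + h & g$dc >= c0 & g$dc < c0 + w
    },
    capsule = {
      a <- s[["angle"]] * pi / 180
      ax <- c(sin(a), cos(a)) * s[["length"]] / 2   # (dr, dc) half-axis
      t <- pmin(1, pmax(-1, (g$dr * ax[1] + g$dc * ax[2]) / sum(ax^2)))
      (g$dr - t * ax[1])^2 + (g$dc - t * ax[2])^2 <= s[["radius"]]^2
    })
  cbind(g$dr[keep], g$dc[keep])
}

# centre (row, col), 0-based, of an object at frame t
objectCenterAt <- function(spec, t)
  spec@center + (t - spec@entryFrame) * spec@velocity

# smooth 0..1 value-noise texture (seeded white noise, Gaussian smoothed)
valueNoiseTexture <- function(H, W, seed, sigma = 2.5) {
  # the Gaussian brush (size 2*ceiling(3*sigma)+1) must fit inside the image
  sigma <- min(sigma, (floor((min(H, W) - 1) / 2) - 0.01) / 3)
  withSeed(seed, {
    n <- matrix(stats::runif(H * W), H, W)
    s <- matrix(as.numeric(EBImage::gblur(n, sigma = sigma)), H, W)
    rng <- range(s)
    (s - rng[1]) / max(rng[2] - rng[1], 1e-12)
  })
}

# texture field translated by an integer offset with wrap-around, so object
# texture moves rigidly with the object
shiftWrap <- function(tex, offR, offC) {
  H <- nrow(tex); W <- ncol(tex)
  ri <- ((seq_len(H) - 1L - round(offR)) %% H) + 1L
  ci <- ((seq_len(W) - 1L - round(offC)) %% W) + 1L
  tex[ri, ci, drop = FALSE]
}

#' Generate a synthetic scene with full ground truth
#'
#' Renders T frames of textured background regions and moving objects,
#' painting later-listed objects on top, and returns the frames together
#' with exact ground-truth label maps, ground-truth flow (objects carry their
#' configured velocity, everything else is static), per-frame ground-truth
#' detections and the entry/exit event log. The output is deterministic given
#' the configuration seeds.
#'
#' @param config a [SceneConfig].
#' @return a [SceneBundle].
#' @examples
#' schema <- LabelSchema(c("tissue", "tool"))
#' cfg <- SceneConfig(32, 32, 6, schema, objects = list(
#'   ObjectSpec(2, "disk", center = c(15, 8), velocity = c(0, 1),
#'              entryFrame = 0, exitFrame = 6, radius = 4)))
#' bundle <- generateScene(cfg)
#' nFrames(bundle@frames)
#' @export
generateScene <- function(config) {
  H <- config@height; W <- config@width; T <- config@nFrames
  schema <- config@schema
  objs <- config@objects
  offs <- lapply(objs, shapeOffsets)
  # trajectory bounds check
  for (i in seq_along(objs)) {
    o <- objs[[i]]
    for (t in o@entryFrame:(o@exitFrame - 1L)) {
      ctr <- objectCenterAt(o, t)
      r <- ctr[1] + offs[[i]][, 1]; cc <- ctr[2] + offs[[i]][, 2]
      if (min(r) < 0 || max(r) > H - 1L || min(cc) < 0 || max(cc) > W - 1L)
        stop(sprintf("object %d exits bounds at frame %d", i - 1L, t),
             call. = FALSE)
    }
  }
  # static background label map (regions painted in list order)
  bgMask <- matrix(0L, H, W)
  bgOffs <- lapply(config@backgroundRegions, shapeOffsets)
  for (i in seq_along(config@backgroundRegions)) {
    o <- config@backgroundRegions[[i]]
    idx <- cbind(o@center[1] + bgOffs[[i]][, 1] + 1L,
                 o@center[2] + bgOffs[[i]][, 2] + 1L)
    idx <- idx[idx[, 1] >= 1 & idx[, 1] <= H & idx[, 2] >= 1 &
               idx[, 2] <= W, , drop = FALSE]
    bgMask[idx] <- o@classId
  }
  # per-frame object label maps and per-object pixel indices
  masks <- vector("list", T)
  objPixels <- vector("list", T)   # list over frames of list over objects
  for (t in seq_len(T) - 1L) {
    m <- bgMask
    op <- vector("list", length(objs))
    for (i in seq_along(objs)) {
      o <- objs[[i]]
      if (t < o@entryFrame || t >= o@exitFrame) next
      ctr <- objectCenterAt(o, t)
      idx <- cbind(round(ctr[1] + offs[[i]][, 1]) + 1L,
                   round(ctr[2] + offs[[i]][, 2]) + 1L)
      m[idx] <- o@classId
      op[[i]] <- idx
    }
    masks[[t + 1L]] <- m
    objPixels[[t + 1L]] <- op
  }
  # exact ground-truth flow: velocity on pixels of objects visible at t and
  # t+1 (painted in depth order), zero elsewhere
  flow <- vector("list", max(T - 1L, 0L))
  for (t in seq_len(T - 1L) - 1L) {
    f <- array(0, c(H, W, 2L))
    for (i in seq_along(objs)) {
      o <- objs[[i]]
      if (t < o@entryFrame || t + 1L >= o@exitFrame) next
      idx <- objPixels[[t + 1L]][[i]]
      f[cbind(idx, 1L)] <- o@velocity[1]
      f[cbind(idx, 2L)] <- o@velocity[2]
    }
    flow[[t + 1L]] <- f
  }
  # rendering: class colour modulated by textures; background texture is
  # static, object texture translates rigidly with the object so dense flow
  # estimators have gradients that follow the true motion
  bgTex <- valueNoiseTexture(H, W, config@textureSeed)
  objTex <- lapply(seq_along(objs), function(i)
    valueNoiseTexture(H, W, config@textureSeed + i))
  pal <- schemaPalette(schema)
  frames <- withSeed(config@noiseSeed, {
    lapply(seq_len(T) - 1L, function(t) {
      m <- masks[[t + 1L]]
      fac <- 0.55 + 0.45 * bgTex
      for (i in seq_along(objs)) {
        idx <- objPixels[[t + 1L]][[i]]
        if (is.null(idx)) next
        o <- objs[[i]]
        off <- (t - o@entryFrame) * o@velocity
        tex <- shiftWrap(objTex[[i]], off[1], off[2])
        keep <- m[idx] == o@classId     # not over-painted by a later object
        idx <- idx[keep, , drop = FALSE]
        fac[idx] <- 0.55 + 0.45 * tex[idx]
      }
      arr <- array(0L, c(H, W, 3L))
      for (ch in 1:3) {
        colour <- matrix(pal[m + 1L, ch], H, W)
        v <- colour * fac + stats::rnorm(H * W, sd = 2)
        arr[, , ch] <- matrix(as.integer(pmin(255, pmax(0, round(v)))), H, W)
      }
      arr
    })
  })
  dets <- lapply(seq_len(T) - 1L, function(t)
    detectionsFromMask(masks[[t + 1L]], schema, frameId = t))
  events <- if (length(objs))
    data.frame(object_id = seq_along(objs) - 1L,
               class_id = vapply(objs, function(o) o@classId, integer(1)),
               entry = vapply(objs, function(o) o@entryFrame, integer(1)),
               exit = vapply(objs, function(o) o@exitFrame, integer(1)))
  else data.frame(object_id = integer(0), class_id = integer(0),
                  entry = integer(0), exit = integer(0))
  new("SceneBundle", frames = FrameSequence(frames),
      masks = MaskSequence(masks), flow = flow, detections = dets,
      events = events, schema = schema, config = config)
}

setMethod("nFrames", "SceneBundle", function(x) nFrames(x@frames))
setMethod("frameDims", "SceneBundle", function(x) frameDims(x@frames))

setMethod("show", "SceneBundle", function(object) {
  d <- frameDims(object)
  cat(sprintf(
    "SceneBundle: %d frames of %d x %d, %d objects, %d background regions\n",
    nFrames(object), d[1], d[2], nrow(object@events),
    length(object@config@backgroundRegions)))
})

#' Write a scene bundle to a run directory
#'
#' Writes frames (\code{frames/}), ground-truth masks + schema sidecar
#' (\code{masks/}), ground-truth flow (\code{flow/}), ground-truth
#' detections (\code{detections.txt}) and the event log (\code{events.txt}).
#'
#' @param bundle a [SceneBundle].
#' @param path output directory.
#' @return the path, invisibly.
#' @export
writeSceneBundle <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeFrameSequence(bundle@frames, file.path(path, "frames"))
  writeMaskSequence(bundle@masks, bundle@schema, file.path(path, "masks"))
  flowDir <- file.path(path, "flow")
  dir.create(flowDir, showWarnings = FALSE)
  for (t in seq_along(bundle@flow))
    writeFlowField(bundle@flow[[t]],
                   file.path(flowDir, sprintf("flow_%06d.tsv", t - 1L)))
  writeDetections(bundle@detections, file.path(path, "detections.txt"))
  writeEventLog(bundle@events, file.path(path, "events.txt"))
  invisible(path)
}

# ---- YAML (de)serialisation of scene configurations

objectToList <- function(o)
  c(list(class_id = o@classId, shape = o@shape),
    as.list(o@size),
    list(center = as.numeric(o@center), velocity = as.numeric(o@velocity),
         entry = o@entryFrame, exit = o@exitFrame))

objectFromList <- function(l, nFrames) {
  ObjectSpec(l$class_id, l$shape,
             center = as.numeric(l$center),
             velocity = if (is.null(l$velocity)) c(0, 0)
                        else as.numeric(l$velocity),
             entryFrame = if (is.null(l$entry)) 0L else l$entry,
             exitFrame = if (is.null(l$exit)) nFrames else l$exit,
             radius = l$radius, height = l$height, width = l$width,
             length = l$length,
             angle = if (is.null(l$angle)) 0 else l$angle)
}

#' Write / read a scene configuration as YAML
#'
#' @param config a [SceneConfig].
#' @param path file path.
#' @export
writeSceneConfig <- function(config, path) {
  schema <- config@schema
  lst <- list(
    height = config@height, width = config@width,
    n_frames = config@nFrames,
    texture_seed = config@textureSeed, noise_seed = config@noiseSeed,
    classes = lapply(seq_len(nClasses(schema)), function(i)
      list(id = i, name = schema@labels[i + 1L])),
    objects = lapply(config@objects, objectToList),
    background_regions = lapply(config@backgroundRegions, objectToList))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeSceneConfig
#' @export
readSceneConfig <- function(path) {
  l <- yaml::read_yaml(path)
  ids <- vapply(l$classes, function(x) as.integer(x$id), integer(1))
  nms <- vapply(l$classes, function(x) as.character(x$name), character(1))
  schema <- LabelSchema(nms[order(ids)])
  SceneConfig(l$height, l$width, l$n_frames, schema,
              objects = lapply(l$objects, objectFromList, l$n_frames),
              backgroundRegions = lapply(l$background_regions,
                                         objectFromList, l$n_frames),
              textureSeed = if (is.null(l$texture_seed)) 1L
                            else l$texture_seed,
              noiseSeed = if (is.null(l$noise_seed)) 2L else l$noise_seed)
}
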