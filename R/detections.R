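# DetectionSet construction, derivation from label maps, noise perturbation
# and the line-based text serialisation.

#' Construct a detection set
#'
#' @param frameId 0-based frame id.
#' @param classIds integer vector of class ids (>= 1).
#' @param scores numeric confidences in \eqn{[0,1]}.
#' @param boxes numeric \code{n x 4} normalised \code{(x_min, y_min, x_max,
#'   y_max)} boxes (half-open).
#' @param masks list of full-frame instance masks in \eqn{[0,1]}.
#' @param dims integer \code{c(H, W)}; needed explicitly when \code{n = 0}.
#' @return a [DetectionSet].
#' @export
DetectionSet <- function(frameId, classIds = integer(0),
                         scores = numeric(0),
                         boxes = matrix(numeric(0), 0, 4), masks = list(),
                         dims = NULL) {
  if (is.null(dims)) {
    if (!length(masks))
      stop("dims must be given for an empty DetectionSet", call. = FALSE)
    dims <- dim(masks[[1]])
  }
  new("DetectionSet", frameId = as.integer(frameId),
      classIds = as.integer(classIds), scores = as.numeric(scores),
      boxes = boxes, masks = masks, dims = as.integer(dims))
}

#' Number of detections
#' @param dets a [DetectionSet].
#' @export
nDetections <- function(dets) length(dets@classIds)

setMethod("show", "DetectionSet", function(object) {
  cat(sprintf("DetectionSet frame %d: %d detections (classes %s)\n",
              object@frameId, nDetections(object),
              classSetLabel(object@classIds)))
})

# tight normalised half-open box of a set of 1-based pixel indices
boxFromPixels <- function(rows, cols, H, W) {
  c((min(cols) - 1L) / W, (min(rows) - 1L) / H, max(cols) / W,
    max(rows) / H)
}

#' Derive ground-truth detections from a semantic label map
#'
#' One detection per 8-connected component per non-background class: the box
#' is the tight half-open bounding box of the component normalised by (W, H),
#' the instance mask is the component indicator and the score is 1. The
#' detection order is deterministic: classes ascending, components in
#' row-major first-pixel order.
#'
#' @param mask integer label map.
#' @param schema the [LabelSchema] the labels belong to.
#' @param frameId 0-based frame id stored in the result.
#' @return a [DetectionSet].
#' @export
detectionsFromMask <- function(mask, schema, frameId = 0L) {
  C <- nClasses(schema)
  if (max(mask) > C) stop("label outside schema", call. = FALSE)
  H <- nrow(mask); W <- ncol(mask)
  classIds <- integer(0); boxes <- NULL; masks <- list()
  for (cls in sort(unique(as.integer(mask[mask > 0L])))) {
    lab <- labelComponents8(mask == cls)
    for (k in seq_len(max(lab))) {
      comp <- lab == k
      px <- which(comp, arr.ind = TRUE)
      classIds <- c(classIds, cls)
      boxes <- rbind(boxes, boxFromPixels(px[, 1], px[, 2], H, W))
      masks <- c(masks, list(matrix(as.numeric(comp), H, W)))
    }
  }
  if (!length(classIds))
    return(DetectionSet(frameId, dims = c(H, W)))
  DetectionSet(frameId, classIds, rep(1, length(classIds)), boxes, masks)
}

# disk raster fully determined by centre (1-based) and radius
diskMask <- function(H, W, r0, c0, radius) {
  (row(matrix(0, H, W)) - r0)^2 + (col(matrix(0, H, W)) - c0)^2 <= radius^2
}

#' Construct a detection noise model
#'
#' @param missProb,spuriousProb,scoreSd see [NoiseConfig-class].
#' @param spuriousDuration inclusive integer range of blip durations.
#' @param jitterRange inclusive integer range of dilation/erosion radii
#'   (\code{c(0, 0)} disables boundary jitter).
#' @param seed RNG seed of the realisation.
#' @return a [NoiseConfig].
#' @export
NoiseConfig <- function(missProb = 0, spuriousProb = 0,
                        spuriousDuration = c(1L, 1L),
                        jitterRange = c(0L, 0L), scoreSd = 0, seed = 1L) {
  new("NoiseConfig", missProb = missProb, spuriousProb = spuriousProb,
      spuriousDuration = as.integer(spuriousDuration),
      jitterRange = as.integer(jitterRange), scoreSd = scoreSd,
      seed = as.integer(seed))
}

emptyRealization <- function()
  data.frame(event = character(0), frame = integer(0), class_id = integer(0),
             detection = integer(0), duration = integer(0))

#' Perturb per-frame detections with a stochastic noise model
#'
#' Applies, in order: whole-detection misses, spurious blips (a small random
#' disk of a random class inserted for a contiguous run of frames),
#' morphological boundary jitter (dilation or erosion of the instance mask
#' with the box recomputed; detections eroded to nothing are dropped) and
#' additive Gaussian score noise. The realisation is fully determined by the
#' [NoiseConfig] seed; the injected events are recorded in the
#' \code{"realization"} attribute of the returned list.
#'
#' @param dets list of [DetectionSet], one per frame.
#' @param noise a [NoiseConfig].
#' @param schema the [LabelSchema] (spurious classes are drawn from it).
#' @return list of perturbed [DetectionSet] with attribute
#'   \code{realization}, a data.frame logging the injected events.
#' @export
perturbDetections <- function(dets, noise, schema) {
  C <- nClasses(schema)
  T <- length(dets)
  dims <- dets[[1]]@dims
  H <- dims[1]; W <- dims[2]
  log <- emptyRealization()
  out <- withSeed(noise@seed, {
    res <- dets
    # pass 1: misses
    if (noise@missProb > 0) {
      for (t in seq_len(T)) {
        d <- res[[t]]
        n <- nDetections(d)
        if (!n) next
        drop <- stats::runif(n) < noise@missProb
        if (any(drop)) {
          for (i in which(drop))
            log <- rbind(log, data.frame(event = "miss", frame = t - 1L,
                                         class_id = d@classIds[i],
                                         detection = i - 1L,
                                         duration = 1L))
          res[[t]] <- DetectionSet(d@frameId, d@classIds[!drop],
                                   d@scores[!drop],
                                   d@boxes[!drop, , drop = FALSE],
                                   d@masks[!drop], dims = dims)
        }
      }
    }
    # pass 2: spurious blips (per class per frame start probability; starts
    # are suppressed while a blip of the same class is active)
    if (noise@spuriousProb > 0) {
      activeUntil <- rep(-1L, C)
      for (t in seq_len(T) - 1L) {
        for (cls in seq_len(C)) {
          if (t <= activeUntil[cls]) next
          if (stats::runif(1) >= noise@spuriousProb) next
          dur <- sample(noise@spuriousDuration[1]:noise@spuriousDuration[2],
                        1L)
          last <- min(t + dur - 1L, T - 1L)
          radius <- sample(2:4, 1L)
          r0 <- sample((radius + 1L):(H - radius), 1L)
          c0 <- sample((radius + 1L):(W - radius), 1L)
          score <- stats::runif(1, 0.7, 1)
          blip <- matrix(as.numeric(diskMask(H, W, r0, c0, radius)), H, W)
          px <- which(blip > 0, arr.ind = TRUE)
          box <- boxFromPixels(px[, 1], px[, 2], H, W)
          for (s in t:last) {
            d <- res[[s + 1L]]
            res[[s + 1L]] <- DetectionSet(d@frameId,
                                          c(d@classIds, cls),
                                          c(d@scores, score),
                                          rbind(d@boxes, box),
                                          c(d@masks, list(blip)),
                                          dims = dims)
          }
          activeUntil[cls] <- last
          log <- rbind(log, data.frame(event = "spurious", frame = t,
                                       class_id = cls, detection = NA,
                                       duration = last - t + 1L))
        }
      }
    }
    # pass 3: boundary jitter
    if (noise@jitterRange[2] > 0L) {
      for (t in seq_len(T)) {
        d <- res[[t]]
        n <- nDetections(d)
        if (!n) next
        keep <- rep(TRUE, n)
        for (i in seq_len(n)) {
          radius <- if (noise@jitterRange[1] == noise@jitterRange[2])
            noise@jitterRange[1]
          else sample(noise@jitterRange[1]:noise@jitterRange[2], 1L)
          if (radius == 0L) next
          op <- sample(c("dilate", "erode"), 1L)
          brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
          m <- matrix(as.numeric(d@masks[[i]] >= 0.5), H, W)
          m2 <- if (op == "dilate") EBImage::dilate(m, brush)
                else EBImage::erode(m, brush)
          m2 <- matrix(as.numeric(m2), H, W)
          if (!any(m2 > 0)) {
            keep[i] <- FALSE
            log <- rbind(log, data.frame(event = "erased", frame = t - 1L,
                                         class_id = d@classIds[i],
                                         detection = i - 1L, duration = 1L))
            next
          }
          px <- which(m2 > 0, arr.ind = TRUE)
          d@masks[[i]] <- m2
          d@boxes[i, ] <- boxFromPixels(px[, 1], px[, 2], H, W)
        }
        res[[t]] <- DetectionSet(d@frameId, d@classIds[keep],
                                 d@scores[keep],
                                 d@boxes[keep, , drop = FALSE],
                                 d@masks[keep], dims = dims)
      }
    }
    # pass 4: score noise
    if (noise@scoreSd > 0) {
      for (t in seq_len(T)) {
        d <- res[[t]]
        n <- nDetections(d)
        if (!n) next
        d@scores <- pmin(1, pmax(0, d@scores +
                                   stats::rnorm(n, sd = noise@scoreSd)))
        res[[t]] <- d
      }
    }
    res
  })
  attr(out, "realization") <- log
  out
}

# ---- line-based text serialisation with row-major run-length encoded masks

rleEncodeMask <- function(mask) {
  v <- as.integer(t(mask) >= 0.5)          # row-major flattening
  r <- rle(v)
  if (r$values[1] == 1L) {
    r$lengths <- c(0L, r$lengths)
    r$values <- c(0L, r$values)
  }
  paste(r$lengths, collapse = ",")
}

rleDecodeMask <- function(code, H, W) {
  lens <- as.integer(strsplit(code, ",", fixed = TRUE)[[1]])
  vals <- rep_len(c(0L, 1L), length(lens))
  v <- rep(vals, lens)
  matrix(v, H, W, byrow = TRUE)
}

#' Serialise detections to a line-based text file
#'
#' Format: a \code{frame <id> <H> <W>} header per frame followed by one
#' \code{det <class> <score> <xmin> <ymin> <xmax> <ymax> <rle>} line per
#' detection, where \code{<rle>} is the row-major run-length encoding of the
#' binarised instance mask (alternating 0/1 run lengths, starting with a
#' 0-run).
#'
#' @param dets list of [DetectionSet].
#' @param path file path.
#' @export
writeDetections <- function(dets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (d in dets) {
    writeLines(sprintf("frame %d %d %d", d@frameId, d@dims[1], d@dims[2]),
               con)
    for (i in seq_len(nDetections(d)))
      writeLines(sprintf("det %d %.17g %.17g %.17g %.17g %.17g %s",
                         d@classIds[i], d@scores[i], d@boxes[i, 1],
                         d@boxes[i, 2], d@boxes[i, 3], d@boxes[i, 4],
                         rleEncodeMask(d@masks[[i]])), con)
  }
  invisible(path)
}

#' @rdname writeDetections
#' @return \code{readDetections}: list of [DetectionSet].
#' @export
readDetections <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    DetectionSet(cur$frameId, cur$classIds, cur$scores,
                 if (length(cur$classIds)) do.call(rbind, cur$boxes)
                 else matrix(numeric(0), 0, 4),
                 cur$masks, dims = cur$dims)
  }
  for (ln in lines) {
    p <- strsplit(ln, " ", fixed = TRUE)[[1]]
    if (p[1] == "frame") {
      if (!is.null(cur)) out <- c(out, list(flush(cur)))
      cur <- list(frameId = as.integer(p[2]),
                  dims = as.integer(p[3:4]), classIds = integer(0),
                  scores = numeric(0), boxes = list(), masks = list())
    } else if (p[1] == "det") {
      cur$classIds <- c(cur$classIds, as.integer(p[2]))
      cur$scores <- c(cur$scores, as.numeric(p[3]))
      cur$boxes <- c(cur$boxes, list(as.numeric(p[4:7])))
      cur$masks <- c(cur$masks,
                     list(rleDecodeMask(p[8], cur$dims[1], cur$dims[2])))
    }
  }
  if (!is.null(cur)) out <- c(out, list(flush(cur)))
  out
}
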