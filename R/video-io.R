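# Frame and mask sequence containers and their on-disk layout.
#
# Canonical storage: a directory of numbered PNGs (frame_%06d.png /
# mask_%06d.png). Frames are 8-bit RGB; masks are single-channel 8-bit PNGs
# whose gray level IS the class id (bit-exact label storage, no colour-table
# ambiguity), accompanied by a schema sidecar carrying names and palette
# colours. All pixel coordinates are (row, col), origin top-left, 0-based;
# frame ids are 0-based.

#' Construct a frame sequence
#'
#' @param frames list of \code{H x W x 3} arrays with intensities 0..255.
#' @param frameIds optional 0-based frame ids (default \code{0:(T-1)}).
#' @return a [FrameSequence].
#' @export
FrameSequence <- function(frames, frameIds = seq_along(frames) - 1L) {
  frames <- lapply(frames, function(f) {
    storage.mode(f) <- "integer"
    f
  })
  new("FrameSequence", frames = frames, frameIds = as.integer(frameIds))
}

#' Construct a mask sequence
#'
#' @param masks list of integer \code{H x W} label matrices.
#' @param frameIds optional 0-based frame ids (default \code{0:(T-1)}).
#' @return a [MaskSequence].
#' @export
MaskSequence <- function(masks, frameIds = seq_along(masks) - 1L) {
  masks <- lapply(masks, function(m) {
    storage.mode(m) <- "integer"
    m
  })
  new("MaskSequence", masks = masks, frameIds = as.integer(frameIds))
}

setMethod("nFrames", "FrameSequence", function(x) length(x@frames))
setMethod("nFrames", "MaskSequence", function(x) length(x@masks))
setMethod("frameIds", "FrameSequence", function(x) x@frameIds)
setMethod("frameIds", "MaskSequence", function(x) x@frameIds)
setMethod("frameDims", "FrameSequence",
          function(x) dim(x@frames[[1]])[1:2])
setMethod("frameDims", "MaskSequence", function(x) dim(x@masks[[1]]))
setMethod("frameDims", "DetectionSet", function(x) x@dims)

setMethod("getFrame", "FrameSequence", function(x, frameId) {
  i <- match(as.integer(frameId), x@frameIds)
  if (is.na(i)) stop(sprintf("unknown frame %d", frameId), call. = FALSE)
  x@frames[[i]]
})

setMethod("getMask", "MaskSequence", function(x, frameId) {
  i <- match(as.integer(frameId), x@frameIds)
  if (is.na(i)) stop(sprintf("unknown frame %d", frameId), call. = FALSE)
  x@masks[[i]]
})

setMethod("show", "FrameSequence", function(object) {
  d <- frameDims(object)
  cat(sprintf("FrameSequence: %d frames of %d x %d (ids %d..%d)\n",
              nFrames(object), d[1], d[2], min(object@frameIds),
              max(object@frameIds)))
})

setMethod("show", "MaskSequence", function(object) {
  d <- frameDims(object)
  cls <- sort(unique(unlist(lapply(object@masks, unique))))
  cat(sprintf("MaskSequence: %d masks of %d x %d; labels {%s}\n",
              nFrames(object), d[1], d[2], paste(cls, collapse = ", ")))
})

# sorted numbered files of one extension inside a directory
listNumbered <- function(path, pattern) {
  files <- list.files(path, pattern = pattern, full.names = TRUE)
  if (!length(files)) return(character(0))
  idx <- as.integer(sub(".*?(\\d+)\\.[A-Za-z]+$", "\\1", basename(files)))
  files[order(idx)]
}

fileFrameId <- function(file)
  as.integer(sub(".*?(\\d+)\\.[A-Za-z]+$", "\\1", basename(file)))

#' Read a frame sequence from a directory of numbered PNGs
#'
#' Frames are ordered by the numeric index embedded in the file name; pixel
#' data are returned unmodified as 0..255 integers.
#'
#' @param path directory containing \code{frame_NNNNNN.png} files.
#' @return a [FrameSequence].
#' @export
readFrameSequence <- function(path) {
  files <- listNumbered(path, "\\.png$")
  if (!length(files)) stop("no frames found in ", path, call. = FALSE)
  frames <- vector("list", length(files))
  ids <- integer(length(files))
  for (i in seq_along(files)) {
    ids[i] <- fileFrameId(files[i])
    px <- tryCatch(png::readPNG(files[i]), error = function(e)
      stop(sprintf("cannot decode frame %d: %s", ids[i], conditionMessage(e)),
           call. = FALSE))
    if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
    px <- px[, , 1:3, drop = FALSE]
    arr <- array(as.integer(round(px * 255)), dim(px))
    if (i > 1L && !identical(dim(arr)[1:2], dim(frames[[1]])[1:2]))
      stop(sprintf("shape mismatch at frame %d", ids[i]), call. = FALSE)
    frames[[i]] <- arr
  }
  FrameSequence(frames, ids)
}

#' Write a frame sequence as numbered PNGs
#'
#' @param frames a [FrameSequence].
#' @param path output directory (created if missing).
#' @return character vector of written files, invisibly.
#' @export
writeFrameSequence <- function(frames, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  out <- character(nFrames(frames))
  for (i in seq_len(nFrames(frames))) {
    out[i] <- file.path(path, sprintf("frame_%06d.png", frames@frameIds[i]))
    png::writePNG(frames@frames[[i]] / 255, out[i])
  }
  invisible(out)
}

#' Write a mask sequence as indexed single-channel PNGs
#'
#' Each label map is stored as an 8-bit single-channel PNG whose gray level
#' equals the class id, so labels round-trip bit-exactly for any schema with
#' C <= 255. The schema sidecar (\code{schema.txt}) is written next to the
#' masks.
#'
#' @param masks a [MaskSequence].
#' @param schema the [LabelSchema]; every mask value must be a valid id.
#' @param path output directory (created if missing).
#' @return character vector of written files, invisibly.
#' @export
writeMaskSequence <- function(masks, schema, path) {
  C <- nClasses(schema)
  if (C > 255L)
    stop("schemas with more than 255 classes exceed 8-bit mask storage",
         call. = FALSE)
  for (i in seq_len(nFrames(masks)))
    if (max(masks@masks[[i]]) > C)
      stop(sprintf("label outside schema at frame %d", masks@frameIds[i]),
           call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  out <- character(nFrames(masks))
  for (i in seq_len(nFrames(masks))) {
    out[i] <- file.path(path, sprintf("mask_%06d.png", masks@frameIds[i]))
    png::writePNG(masks@masks[[i]] / 255, out[i])
  }
  writeLabelSchema(schema, file.path(path, "schema.txt"))
  invisible(out)
}

#' Read a mask sequence written by [writeMaskSequence()]
#'
#' @param path directory of \code{mask_NNNNNN.png} files.
#' @param schema the [LabelSchema] the stored indices must belong to.
#' @return a [MaskSequence] with values exactly equal to the stored indices.
#' @export
readMaskSequence <- function(path, schema) {
  files <- listNumbered(path, "^mask_\\d+\\.png$")
  if (!length(files)) stop("no masks found in ", path, call. = FALSE)
  C <- nClasses(schema)
  masks <- vector("list", length(files))
  ids <- integer(length(files))
  for (i in seq_along(files)) {
    ids[i] <- fileFrameId(files[i])
    px <- tryCatch(png::readPNG(files[i]), error = function(e)
      stop(sprintf("cannot decode mask %d: %s", ids[i], conditionMessage(e)),
           call. = FALSE))
    if (length(dim(px)) == 3L)
      stop(sprintf("mask not single-channel indexed at frame %d", ids[i]),
           call. = FALSE)
    m <- matrix(as.integer(round(px * 255)), nrow(px), ncol(px))
    if (max(m) > C)
      stop(sprintf("label outside schema at frame %d", ids[i]),
           call. = FALSE)
    masks[[i]] <- m
  }
  MaskSequence(masks, ids)
}

# ---- plain-text flow field storage (2H x W tab-separated: drow then dcol)

#' Write / read a flow field as tab-separated text
#'
#' The \code{H x W x 2} displacement array is stored as a \code{2H x W}
#' table: the first H rows hold drow, the next H rows dcol.
#'
#' @param flow numeric \code{H x W x 2} array (drow, dcol) in pixels.
#' @param path file path.
#' @export
writeFlowField <- function(flow, path) {
  m <- rbind(flow[, , 1], flow[, , 2])
  utils::write.table(format(m, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeFlowField
#' @export
readFlowField <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  H <- nrow(m) %/% 2L
  dimnames(m) <- NULL
  array(c(m[seq_len(H), ], m[H + seq_len(H), ]), c(H, ncol(m), 2L))
}

# ---- entry/exit event log

#' Write / read the scene event log
#'
#' One line per object: \code{object_id class_id entry exit} (0-based frames,
#' half-open window).
#'
#' @param events data.frame with columns object_id, class_id, entry, exit.
#' @param path file path.
#' @export
writeEventLog <- function(events, path) {
  lines <- c("# object_id class_id entry exit",
             sprintf("%d %d %d %d", events$object_id, events$class_id,
                     events$entry, events$exit))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeEventLog
#' @export
readEventLog <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(object_id = integer(0), class_id = integer(0),
                      entry = integer(0), exit = integer(0)))
  m <- do.call(rbind, lapply(strsplit(lines, " +"), as.integer))
  data.frame(object_id = m[, 1], class_id = m[, 2], entry = m[, 3],
             exit = m[, 4])
}
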