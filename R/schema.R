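#' Construct a label schema
#'
#' @param classes character vector of the C non-background class names, in
#'   id order (ids 1..C).
#' @param background name of the background class (id 0).
#' @param palette optional \code{(C+1) x 3} RGB matrix (0..255); by default a
#'   deterministic palette with black background and evenly spaced hues.
#' @return a [LabelSchema].
#' @examples
#' schema <- LabelSchema(c("tissue", "grasper", "hook"))
#' nClasses(schema)
#' @export
LabelSchema <- function(classes, background = "background", palette = NULL) {
  C <- length(classes)
  if (is.null(palette)) {
    hues <- (seq_len(C) - 1) / max(C, 1)
    cols <- t(grDevices::col2rgb(grDevices::hsv(hues, 0.75, 0.95)))
    palette <- rbind(c(0L, 0L, 0L), cols)
  }
  storage.mode(palette) <- "integer"
  dimnames(palette) <- NULL
  new("LabelSchema", ids = 0:C, labels = c(background, classes),
      palette = palette)
}

#' Number of non-background classes C
#' @param schema a [LabelSchema].
#' @export
nClasses <- function(schema) length(schema@ids) - 1L

#' Class names of a schema
#' @param schema a [LabelSchema].
#' @param ids optional class ids to look up.
#' @export
classNames <- function(schema, ids = NULL) {
  if (is.null(ids)) return(schema@labels)
  schema@labels[match(ids, schema@ids)]
}

#' Palette colours of a schema
#' @param schema a [LabelSchema].
#' @return integer \code{(C+1) x 3} RGB matrix.
#' @export
schemaPalette <- function(schema) schema@palette

setMethod("show", "LabelSchema", function(object) {
  cat(sprintf("LabelSchema with %d classes + background\n",
              nClasses(object)))
  cat(paste(sprintf("  %d: %s", object@ids, object@labels), collapse = "\n"),
      "\n")
})

#' Write / read the schema sidecar file
#'
#' Plain-text key-value format, one class per line:
#' \code{id<TAB>name<TAB>R,G,B}.
#'
#' @param schema a [LabelSchema].
#' @param path file path of the sidecar.
#' @return \code{writeLabelSchema}: the path, invisibly;
#'   \code{readLabelSchema}: a [LabelSchema].
#' @export
writeLabelSchema <- function(schema, path) {
  lines <- c("# label schema: id\tname\tR,G,B",
             sprintf("%d\t%s\t%d,%d,%d", schema@ids, schema@labels,
                     schema@palette[, 1], schema@palette[, 2],
                     schema@palette[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeLabelSchema
#' @export
readLabelSchema <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  labs <- vapply(parts, function(p) p[2], character(1))
  pal <- t(vapply(parts,
                  function(p) as.integer(strsplit(p[3], ",")[[1]]),
                  integer(3)))
  ord <- order(ids)
  new("LabelSchema", ids = ids[ord], labels = labs[ord],
      palette = pal[ord, , drop = FALSE])
}
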