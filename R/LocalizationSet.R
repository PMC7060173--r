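#' Construct a localization set
#'
#' @param x,y Numeric vectors of coordinates in nm.
#' @param frames Integer vector of 1-based acquisition-frame indices; a
#'   single value is recycled. Defaults to frame 1 for every record.
#' @param channelId Character label for the color channel.
#' @param roi A [RegionOfInterest-class]; if `NULL`, the bounding box of
#'   the data (expanded by a hair on the open edges so all points are
#'   members).
#' @return A [LocalizationSet-class].
#' @examples
#' ls <- LocalizationSet(c(0, 10, 5), c(0, 20, 5), channelId = "red")
#' nLocalizations(ls)
#' @export
LocalizationSet <- function(x, y, frames = 1L, channelId = "points",
                            roi = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have the same length")
  frames <- as.integer(frames)
  if (length(frames) == 1L) frames <- rep(frames, length(x))
  if (is.null(roi)) roi <- .boundingRoi(x, y)
  coords <- cbind(x = x, y = y)
  new("LocalizationSet", channelId = as.character(channelId),
      coords = coords, frames = frames, roi = roi)
}

# bounding box as an ROI; max edges nudged outward so membership is
# half-open yet every observed point is inside
.boundingRoi <- function(x, y) {
  if (length(x) == 0L) stop("cannot derive an ROI from an empty set")
  eps <- function(v) max(1e-6, abs(v) * 1e-9)
  xmax <- max(x); ymax <- max(y)
  RegionOfInterest(min(x), min(y), xmax + eps(xmax), ymax + eps(ymax))
}

#' @rdname clasta-accessors
#' @export
setMethod("coords", "LocalizationSet", function(object, ...) object@coords)

#' @rdname clasta-accessors
#' @export
setMethod("frames", "LocalizationSet", function(object, ...) object@frames)

#' @rdname clasta-accessors
#' @export
setMethod("channelId", "LocalizationSet",
          function(object, ...) object@channelId)

#' @rdname clasta-accessors
#' @export
setMethod("roi", "LocalizationSet", function(object, ...) object@roi)

#' Number of localizations in a set
#'
#' @param object A [LocalizationSet-class].
#' @return Integer count.
#' @export
nLocalizations <- function(object) {
  stopifnot(is(object, "LocalizationSet"))
  nrow(object@coords)
}

#' @rdname clasta-accessors
#' @export
setMethod("length", "LocalizationSet", function(x) nrow(x@coords))

#' Subset a localization set
#'
#' @param x A [LocalizationSet-class].
#' @param i Row index (logical or integer).
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "LocalizationSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, coords = x@coords[i, , drop = FALSE], frames = x@frames[i])
})

setMethod("show", "LocalizationSet", function(object) {
  n <- nrow(object@coords)
  cat(sprintf("LocalizationSet '%s': %d localizations\n",
              object@channelId, n))
  if (n > 0L) {
    cat(sprintf("  x: [%.1f, %.1f] nm  y: [%.1f, %.1f] nm  frames: [%d, %d]\n",
                min(object@coords[, 1]), max(object@coords[, 1]),
                min(object@coords[, 2]), max(object@coords[, 2]),
                min(object@frames), max(object@frames)))
  }
  cat("  ")
  show(object@roi)
})

#' Coerce a localization set to a data.frame
#'
#' @param x A [LocalizationSet-class].
#' @param ... Ignored.
#' @return `data.frame` with columns `x`, `y`, `frame` (nm, nm, index).
#' @export
setMethod("as.data.frame", "LocalizationSet", function(x, ...) {
  data.frame(x = x@coords[, 1], y = x@coords[, 2], frame = x@frames)
})

.assertNonEmpty <- function(ls, what = "localization set") {
  if (nLocalizations(ls) == 0L)
    stop(sprintf("empty %s: statistical operations need at least one record",
                 what))
  invisible(ls)
}
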