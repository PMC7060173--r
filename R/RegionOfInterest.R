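#' Construct a region of interest
#'
#' @param xMin,yMin,xMax,yMax Rectangle bounds in nm.
#' @return A [RegionOfInterest-class] object.
#' @examples
#' roi <- RegionOfInterest(0, 0, 10000, 10000)  # 10 x 10 um^2
#' roiArea(roi) / 1e6                           # area in um^2
#' @export
RegionOfInterest <- function(xMin, yMin, xMax, yMax) {
  new("RegionOfInterest", xMin = as.numeric(xMin), yMin = as.numeric(yMin),
      xMax = as.numeric(xMax), yMax = as.numeric(yMax))
}

#' @rdname clasta-accessors
#' @export
setMethod("roiWidth", "RegionOfInterest",
          function(object, ...) object@xMax - object@xMin)

#' @rdname clasta-accessors
#' @export
setMethod("roiHeight", "RegionOfInterest",
          function(object, ...) object@yMax - object@yMin)

#' @rdname clasta-accessors
#' @export
setMethod("roiArea", "RegionOfInterest",
          function(object, ...) roiWidth(object) * roiHeight(object))

#' Rectangle bounds of a region of interest
#'
#' @param object A [RegionOfInterest-class].
#' @return Named numeric vector `c(xMin, yMin, xMax, yMax)` in nm.
#' @export
roiBounds <- function(object) {
  stopifnot(is(object, "RegionOfInterest"))
  c(xMin = object@xMin, yMin = object@yMin,
    xMax = object@xMax, yMax = object@yMax)
}

setMethod("show", "RegionOfInterest", function(object) {
  cat(sprintf("RegionOfInterest [%g, %g) x [%g, %g) nm (%.3g um^2)\n",
              object@xMin, object@xMax, object@yMin, object@yMax,
              roiArea(object) / 1e6))
})

# half-open membership [min, max)
.inRoi <- function(x, y, roi) {
  x >= roi@xMin & x < roi@xMax & y >= roi@yMin & y < roi@yMax
}

.sameRoi <- function(a, b, tol = 1e-6) {
  all(abs(roiBounds(a) - roiBounds(b)) <= tol)
}
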