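#' @name clasta-accessors
#' @title Accessors for clasta classes
#' @param object,x A clasta S4 object.
#' @param ... Ignored.
#' @description Accessor generics for the core containers: coordinates,
#'   frames, channel label and ROI of a [LocalizationSet]; bounds, width,
#'   height and area of a [RegionOfInterest]; p-value and control
#'   statistics of a [ClastaResult]; sensitivity and p-values of a
#'   [PowerResult].
NULL

#' @rdname clasta-accessors
#' @export
setGeneric("coords", function(object, ...) standardGeneric("coords"))

#' @rdname clasta-accessors
#' @export
setGeneric("frames", function(object, ...) standardGeneric("frames"))

#' @rdname clasta-accessors
#' @export
setGeneric("channelId", function(object, ...) standardGeneric("channelId"))

#' @rdname clasta-accessors
#' @export
setGeneric("roi", function(object, ...) standardGeneric("roi"))

#' @rdname clasta-accessors
#' @export
setGeneric("roiWidth", function(object, ...) standardGeneric("roiWidth"))

#' @rdname clasta-accessors
#' @export
setGeneric("roiHeight", function(object, ...) standardGeneric("roiHeight"))

#' @rdname clasta-accessors
#' @export
setGeneric("roiArea", function(object, ...) standardGeneric("roiArea"))

#' @rdname clasta-accessors
#' @export
setGeneric("pValue", function(object, ...) standardGeneric("pValue"))

#' @rdname clasta-accessors
#' @export
setGeneric("gData", function(object, ...) standardGeneric("gData"))

#' @rdname clasta-accessors
#' @export
setGeneric("gControls", function(object, ...) standardGeneric("gControls"))

#' @rdname clasta-accessors
#' @export
setGeneric("rMaxUsed", function(object, ...) standardGeneric("rMaxUsed"))

#' @rdname clasta-accessors
#' @export
setGeneric("sensitivity", function(object, ...) standardGeneric("sensitivity"))

#' @rdname clasta-accessors
#' @export
setGeneric("pValues", function(object, ...) standardGeneric("pValues"))
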