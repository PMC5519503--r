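#' @rdname accessors
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname accessors
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname accessors
#' @export
setGeneric("tracer", function(x) standardGeneric("tracer"))

#' @rdname accessors
#' @export
setGeneric("scaleIndex", function(x) standardGeneric("scaleIndex"))

#' @rdname accessors
#' @export
setGeneric("fcMatrix", function(x) standardGeneric("fcMatrix"))

#' @rdname accessors
#' @export
setGeneric("syncValues", function(x) standardGeneric("syncValues"))

#' @rdname accessors
#' @export
setGeneric("phaseArray", function(x) standardGeneric("phaseArray"))

#' @rdname accessors
#' @export
setGeneric("scaleBands", function(x) standardGeneric("scaleBands"))

#' @rdname accessors
#' @export
setGeneric("boundaryMask", function(x) standardGeneric("boundaryMask"))
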