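#' Accessors for trace and profile classes
#'
#' Small accessor generics so downstream code never touches slots
#' directly.
#'
#' @param x an object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))
#' @rdname accessors
#' @export
setGeneric("tracePosition", function(x) standardGeneric("tracePosition"))
#' @rdname accessors
#' @export
setGeneric("eyeLabel", function(x) standardGeneric("eyeLabel"))
#' @rdname accessors
#' @export
setGeneric("rawF", function(x) standardGeneric("rawF"))
#' @rdname accessors
#' @export
setGeneric("dFF", function(x) standardGeneric("dFF"))
#' @rdname accessors
#' @export
setGeneric("deconv", function(x) standardGeneric("deconv"))
#' @rdname accessors
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))
#' @rdname accessors
#' @export
setGeneric("cellMetadata", function(x) standardGeneric("cellMetadata"))
#' @rdname accessors
#' @export
setGeneric("staMean", function(x) standardGeneric("staMean"))
#' @rdname accessors
#' @export
setGeneric("staTrials", function(x) standardGeneric("staTrials"))
#' @rdname accessors
#' @export
setGeneric("staGrid", function(x) standardGeneric("staGrid"))
#' @rdname accessors
#' @export
setGeneric("isEligible", function(x) standardGeneric("isEligible"))

#' @rdname accessors
setMethod("traceTime", "EyeTrace", function(x) x@time)
#' @rdname accessors
setMethod("traceTime", "CellTrace", function(x) x@time)
#' @rdname accessors
setMethod("tracePosition", "EyeTrace", function(x) x@position)
#' @rdname accessors
setMethod("eyeLabel", "EyeTrace", function(x) x@eye)
#' @rdname accessors
setMethod("rawF", "CellTrace", function(x) x@F)
#' @rdname accessors
setMethod("dFF", "CellTrace", function(x) x@dFF)
#' @rdname accessors
setMethod("deconv", "CellTrace", function(x) x@deconv)
#' @rdname accessors
setMethod("cellId", "CellTrace", function(x) x@cellId)
#' @rdname accessors
setMethod("cellMetadata", "CellTrace", function(x) x@metadata)
#' @rdname accessors
setMethod("staMean", "STAProfile", function(x) x@mean)
#' @rdname accessors
setMethod("staTrials", "STAProfile", function(x) x@trials)
#' @rdname accessors
setMethod("staGrid", "STAProfile", function(x) x@grid)
#' @rdname accessors
setMethod("isEligible", "STAProfile", function(x) x@eligible)

#' Number of samples in a trace
#'
#' @param x an [EyeTrace-class] or [CellTrace-class].
#' @export
setMethod("length", "EyeTrace", function(x) length(x@time))
#' @rdname length-EyeTrace-method
#' @export
setMethod("length", "CellTrace", function(x) length(x@time))
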