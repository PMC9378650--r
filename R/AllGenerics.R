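#' @include AllClasses.R
NULL

#' Accessors for TemperatureSeries and WeibullFit
#'
#' @param x a [TemperatureSeries-class] or [WeibullFit-class] object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))
#' @rdname accessors
#' @export
setGeneric("tempC", function(x) standardGeneric("tempC"))
#' @rdname accessors
#' @export
setGeneric("tankId", function(x) standardGeneric("tankId"))
#' @rdname accessors
#' @export
setGeneric("treatment", function(x) standardGeneric("treatment"))
#' @rdname accessors
#' @export
setGeneric("effectiveDose", function(x) standardGeneric("effectiveDose"))
#' @rdname accessors
#' @export
setGeneric("effectiveDoseSE", function(x) standardGeneric("effectiveDoseSE"))
#' @rdname accessors
#' @export
setGeneric("fitGroup", function(x) standardGeneric("fitGroup"))

#' @rdname accessors
setMethod("timestamps", "TemperatureSeries", function(x) x@timestamps)
#' @rdname accessors
setMethod("tempC", "TemperatureSeries", function(x) x@tempC)
#' @rdname accessors
setMethod("tankId", "TemperatureSeries", function(x) x@tankId)
#' @rdname accessors
setMethod("treatment", "TemperatureSeries", function(x) x@treatment)
#' @rdname accessors
setMethod("effectiveDose", "WeibullFit", function(x) x@ed)
#' @rdname accessors
setMethod("effectiveDoseSE", "WeibullFit", function(x) x@edSE)
#' @rdname accessors
setMethod("fitGroup", "WeibullFit", function(x) x@group)
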