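#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setGeneric("percent", function(x) standardGeneric("percent"))
#' @rdname accessors
#' @export
setGeneric("successes", function(x) standardGeneric("successes"))
#' @rdname accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("stars", function(x) standardGeneric("stars"))
#' @rdname accessors
#' @export
setGeneric("signalRadius", function(x) standardGeneric("signalRadius"))
#' @rdname accessors
#' @export
setGeneric("signalRadius<-", function(x, value) standardGeneric("signalRadius<-"))
#' @rdname accessors
#' @export
setGeneric("territoryRadius", function(x) standardGeneric("territoryRadius"))
#' @rdname accessors
#' @export
setGeneric("territoryRadius<-",
           function(x, value) standardGeneric("territoryRadius<-"))
#' @rdname accessors
#' @export
setGeneric("nucleusAxes", function(x) standardGeneric("nucleusAxes"))
#' @rdname accessors
#' @export
setGeneric("ploidyLabel", function(x) standardGeneric("ploidyLabel"))
#' @rdname accessors
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))
#' @rdname accessors
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))
#' @rdname accessors
#' @export
setGeneric("nucleusIds", function(x) standardGeneric("nucleusIds"))
#' @rdname accessors
#' @export
setGeneric("contingencyTable", function(x) standardGeneric("contingencyTable"))
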