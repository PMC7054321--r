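#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname accessors
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))

#' @rdname accessors
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))

#' @rdname accessors
#' @export
setGeneric("outcomeType", function(x) standardGeneric("outcomeType"))

#' @rdname accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname accessors
#' @export
setGeneric("getOutcome", function(x) standardGeneric("getOutcome"))

#' @rdname accessors
#' @export
setGeneric("activeSet", function(x) standardGeneric("activeSet"))

#' @rdname accessors
#' @export
setGeneric("isSelected", function(x) standardGeneric("isSelected"))

#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))

#' @rdname accessors
#' @export
setGeneric("aggregateMetrics", function(x) standardGeneric("aggregateMetrics"))

#' @rdname accessors
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))
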