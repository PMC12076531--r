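#' @rdname QuantReport-accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname QuantReport-accessors
#' @export
setGeneric("firstAccessions", function(x) standardGeneric("firstAccessions"))

#' @rdname QuantReport-accessors
#' @export
setGeneric("intensityMethods", function(x) standardGeneric("intensityMethods"))

#' @rdname QuantReport-accessors
#' @export
setGeneric("sampleLabels", function(x, method) standardGeneric("sampleLabels"))

#' @rdname QuantReport-accessors
#' @export
setGeneric("intensityMatrix", function(x, method) standardGeneric("intensityMatrix"))

#' @rdname QuantReport-accessors
#' @export
setGeneric("imputedMask", function(x, method) standardGeneric("imputedMask"))

#' @rdname QuantReport-accessors
#' @export
setGeneric("molWeights", function(x) standardGeneric("molWeights"))

#' @rdname SampleGrouping-accessors
#' @export
setGeneric("groupList", function(x) standardGeneric("groupList"))

#' @rdname AnchorSet-accessors
#' @export
setGeneric("anchorAmounts", function(x) standardGeneric("anchorAmounts"))

#' @rdname CalibrationModel-accessors
#' @export
setGeneric("calibrationCoefficients", function(x) standardGeneric("calibrationCoefficients"))

#' @rdname AbsoluteQuantResult-accessors
#' @export
setGeneric("quantTable", function(x) standardGeneric("quantTable"))

#' @rdname AbsoluteQuantResult-accessors
#' @export
setGeneric("calibrationModels", function(x) standardGeneric("calibrationModels"))

#' @rdname ExperimentalParams-accessors
#' @export
setGeneric("paramsTable", function(x) standardGeneric("paramsTable"))

#' @rdname EnrichmentFactor-accessors
#' @export
setGeneric("enrichmentValue", function(x) standardGeneric("enrichmentValue"))
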