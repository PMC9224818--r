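#' @rdname cohortValues
#' @export
setGeneric("cohortValues", function(x) standardGeneric("cohortValues"))

#' @rdname cohortValues
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname cohortValues
#' @export
setGeneric("isCase", function(x) standardGeneric("isCase"))

#' @rdname cohortValues
#' @export
setGeneric("varNames", function(x) standardGeneric("varNames"))

#' @rdname cohortValues
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname markerPrevalence
#' @export
setGeneric("markerPrevalence", function(x, ...) standardGeneric("markerPrevalence"))

#' @rdname ledgerModels
#' @export
setGeneric("ledgerModels", function(x) standardGeneric("ledgerModels"))

#' @rdname ledgerModels
#' @export
setGeneric("nEvaluated", function(x) standardGeneric("nEvaluated"))

#' @rdname networkEdges
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname networkEdges
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))
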