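#' @rdname resultTable
#' @export
setGeneric("resultTable", function(object, ...) standardGeneric("resultTable"))

#' @rdname deCalls
#' @export
setGeneric("deCalls", function(object, ...) standardGeneric("deCalls"))

#' @rdname vennCounts
#' @export
setGeneric("vennCounts", function(object, ...) standardGeneric("vennCounts"))

#' @rdname cellMembers
#' @export
setGeneric("cellMembers", function(object, cell, ...) standardGeneric("cellMembers"))

#' @rdname commonCount
#' @export
setGeneric("commonCount", function(object, ...) standardGeneric("commonCount"))

#' @rdname predictions
#' @export
setGeneric("predictions", function(object, ...) standardGeneric("predictions"))

#' @rdname syntheticTruth
#' @export
setGeneric("syntheticTruth", function(object, ...) standardGeneric("syntheticTruth"))

#' @rdname motifFraction
#' @export
setGeneric("motifFraction", function(object, ...) standardGeneric("motifFraction"))

#' @rdname motifPositions
#' @export
setGeneric("motifPositions", function(object, ...) standardGeneric("motifPositions"))

#' @rdname panelExprs
#' @export
setGeneric("panelExprs", function(object, ...) standardGeneric("panelExprs"))

#' @rdname panelLabels
#' @export
setGeneric("panelLabels", function(object, ...) standardGeneric("panelLabels"))
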