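#' @import methods
NULL

#' @export
setGeneric("bodyMapSize", function(x) standardGeneric("bodyMapSize"))

#' @export
setGeneric("locationIds", function(x) standardGeneric("locationIds"))

#' @export
setGeneric("lookupLocation", function(x, id) standardGeneric("lookupLocation"))

#' @export
setGeneric("manifestRecords", function(x) standardGeneric("manifestRecords"))

#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @export
setGeneric("trainSet", function(x) standardGeneric("trainSet"))

#' @export
setGeneric("valSet", function(x) standardGeneric("valSet"))

#' @export
setGeneric("testSet", function(x) standardGeneric("testSet"))

#' @export
setGeneric("splitMetadata", function(x) standardGeneric("splitMetadata"))

#' @export
setGeneric("netConfig", function(x) standardGeneric("netConfig"))

#' @export
setGeneric("countParameters", function(x) standardGeneric("countParameters"))

#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

#' @export
setGeneric("weightedMetrics", function(x) standardGeneric("weightedMetrics"))

#' @export
setGeneric("macroMetrics", function(x) standardGeneric("macroMetrics"))

#' @export
setGeneric("rocCurves", function(x) standardGeneric("rocCurves"))

#' @export
setGeneric("camHeatmap", function(x) standardGeneric("camHeatmap"))

#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @export
setGeneric("fittedNetwork", function(x) standardGeneric("fittedNetwork"))
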