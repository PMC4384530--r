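#' @include AllClasses.R
NULL

#' @rdname ScreenTensor-class
#' @export
setGeneric("tensorValues", function(x) standardGeneric("tensorValues"))

#' @rdname ScreenTensor-class
#' @export
setGeneric("targetGenes", function(x) standardGeneric("targetGenes"))

#' @rdname ScreenTensor-class
#' @export
setGeneric("queryGenes", function(x) standardGeneric("queryGenes"))

#' @rdname ScreenTensor-class
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname ScreenTensor-class
#' @export
setGeneric("isTransformed", function(x) standardGeneric("isTransformed"))

#' @rdname VstParams-class
#' @export
setGeneric("vstLambda", function(x) standardGeneric("vstLambda"))

#' Apply the variance-stabilising transformation
#'
#' @param x object holding raw-scale values (a \linkS4class{ScreenTensor}, a
#'   matrix with features in columns, or a numeric vector for a single
#'   feature).
#' @param params a \linkS4class{VstParams} object.
#' @param ... further arguments (for the numeric method, \code{feature}: the
#'   feature name whose cofactor should be used).
#' @return an object of the same shape on the transformed scale.
#' @seealso [estimateVstParams()], [inverseVst()]
#' @export
setGeneric("applyVst", function(x, params, ...) standardGeneric("applyVst"))

#' Invert the variance-stabilising transformation
#'
#' @inheritParams applyVst
#' @return an object of the same shape on the raw scale.
#' @export
setGeneric("inverseVst", function(x, params, ...) standardGeneric("inverseVst"))

#' @rdname QcReport-class
#' @export
setGeneric("featureStats", function(x) standardGeneric("featureStats"))

#' @rdname QcReport-class
#' @export
setGeneric("geneStats", function(x) standardGeneric("geneStats"))

#' @rdname QcReport-class
#' @export
setGeneric("passingFeatures", function(x) standardGeneric("passingFeatures"))

#' @rdname QcReport-class
#' @export
setGeneric("passingGenes", function(x) standardGeneric("passingGenes"))

#' @rdname MainEffects-class
#' @export
setGeneric("targetEffects", function(x) standardGeneric("targetEffects"))

#' @rdname MainEffects-class
#' @export
setGeneric("queryEffects", function(x) standardGeneric("queryEffects"))

#' @rdname MainEffects-class
#' @export
setGeneric("effectIntercept", function(x) standardGeneric("effectIntercept"))

#' @rdname MainEffects-class
#' @export
setGeneric("piScores", function(x) standardGeneric("piScores"))

#' @rdname InteractionStats-class
#' @export
setGeneric("interactionTable", function(x) standardGeneric("interactionTable"))

#' @rdname InteractionStats-class
#' @export
setGeneric("priorDf", function(x) standardGeneric("priorDf"))

#' @rdname InteractionStats-class
#' @export
setGeneric("priorVar", function(x) standardGeneric("priorVar"))

#' @rdname FeatureSelectionResult-class
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname FeatureSelectionResult-class
#' @export
setGeneric("selectionSteps", function(x) standardGeneric("selectionSteps"))

#' @rdname CorrelationGraph-class
#' @export
setGeneric("interactionGraph", function(x) standardGeneric("interactionGraph"))

#' @rdname CorrelationGraph-class
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
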