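#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname ScreenTensor-class
#' @export
setMethod("tensorValues", "ScreenTensor", function(x) x@values)

#' @rdname ScreenTensor-class
#' @export
setMethod("targetGenes", "ScreenTensor", function(x) dimnames(x@values)[[1L]])

#' @rdname ScreenTensor-class
#' @export
setMethod("queryGenes", "ScreenTensor", function(x) dimnames(x@values)[[3L]])

#' @rdname ScreenTensor-class
#' @export
setMethod("featureNames", "ScreenTensor", function(x) dimnames(x@values)[[5L]])

#' @rdname ScreenTensor-class
#' @export
setMethod("isTransformed", "ScreenTensor", function(x) x@transformed)

#' @rdname ScreenTensor-class
#' @export
setMethod("dim", "ScreenTensor", function(x) dim(x@values))

setMethod("show", "ScreenTensor", function(object) {
  d <- dim(object@values)
  cat("ScreenTensor:", d[1L], "targets x", d[3L], "queries x",
      "2 x 2 dsRNA designs x", d[5L], "features\n")
  cat("  scale:", if (object@transformed) "variance-stabilised" else "raw",
      "\n")
  cat("  missing values:", sum(is.na(object@values)), "of",
      length(object@values), "\n")
})

#' @rdname VstParams-class
#' @export
setMethod("vstLambda", "VstParams", function(x) x@lambda)

setMethod("show", "VstParams", function(object) {
  cat("VstParams for", length(object@lambda), "features\n")
  cat("  lambda range: [", format(min(object@lambda), digits = 4), ", ",
      format(max(object@lambda), digits = 4), "]\n", sep = "")
})

#' @rdname QcReport-class
#' @export
setMethod("featureStats", "QcReport", function(x) x@featureStats)

#' @rdname QcReport-class
#' @export
setMethod("geneStats", "QcReport", function(x) x@geneStats)

#' @rdname QcReport-class
#' @export
setMethod("passingFeatures", "QcReport", function(x)
  x@featureStats$feature[x@featureStats$status == "pass"])

#' @rdname QcReport-class
#' @export
setMethod("passingGenes", "QcReport", function(x)
  x@geneStats$gene[x@geneStats$status == "pass"])

setMethod("show", "QcReport", function(object) {
  fs <- object@featureStats; gs <- object@geneStats
  cat("QcReport\n")
  if (nrow(fs))
    cat(sprintf("  features: %d pass / %d fail / %d insufficient (r > %.2f)\n",
                sum(fs$status == "pass"), sum(fs$status == "fail"),
                sum(fs$status == "insufficient"), object@featureThreshold))
  if (nrow(gs))
    cat(sprintf("  genes:    %d pass / %d fail / %d insufficient (r > %.2f)\n",
                sum(gs$status == "pass"), sum(gs$status == "fail"),
                sum(gs$status == "insufficient"), object@geneThreshold))
  if (!nrow(fs) && !nrow(gs)) cat("  (empty)\n")
})

#' @rdname MainEffects-class
#' @export
setMethod("targetEffects", "MainEffects", function(x) x@target)

#' @rdname MainEffects-class
#' @export
setMethod("queryEffects", "MainEffects", function(x) x@query)

#' @rdname MainEffects-class
#' @export
setMethod("effectIntercept", "MainEffects", function(x) x@intercept)

#' @rdname MainEffects-class
#' @export
setMethod("piScores", "MainEffects", function(x) x@pi)

setMethod("show", "MainEffects", function(object) {
  d <- dim(object@pi)
  cat("MainEffects (two-way median polish)\n")
  cat("  ", d[1L], " targets x ", d[3L], " queries x ", d[5L],
      " features\n", sep = "")
  cat("  |pi| quartiles:",
      paste(format(quantile(abs(object@pi), c(0.25, 0.5, 0.75), na.rm = TRUE),
                   digits = 3), collapse = " / "), "\n")
  if (length(object@flaggedTargets) || length(object@flaggedQueries))
    cat("  flagged genes (>50% missing):",
        length(object@flaggedTargets), "targets,",
        length(object@flaggedQueries), "queries\n")
})

#' @rdname InteractionStats-class
#' @export
setMethod("interactionTable", "InteractionStats", function(x) x@table)

#' @rdname InteractionStats-class
#' @export
setMethod("priorDf", "InteractionStats", function(x) x@priorDf)

#' @rdname InteractionStats-class
#' @export
setMethod("priorVar", "InteractionStats", function(x) x@priorVar)

setMethod("show", "InteractionStats", function(object) {
  tb <- object@table
  cat("InteractionStats:", length(unique(paste(tb$target, tb$query))),
      "gene pairs x", length(unique(tb$feature)), "features\n")
  cat("  significant at FDR 0.01:",
      sum(tb$p_adj < 0.01, na.rm = TRUE), "pair-feature entries\n")
  cat("  prior df d0: ",
      paste(format(range(object@priorDf), digits = 3), collapse = " - "),
      "\n", sep = "")
})

#' @rdname FeatureSelectionResult-class
#' @export
setMethod("selectedFeatures", "FeatureSelectionResult", function(x) x@selected)

#' @rdname FeatureSelectionResult-class
#' @export
setMethod("selectionSteps", "FeatureSelectionResult", function(x) x@steps)

setMethod("show", "FeatureSelectionResult", function(object) {
  cat("FeatureSelectionResult:", length(object@selected), "features (",
      length(object@seeds), "seeds +",
      length(object@selected) - length(object@seeds), "selected )\n")
  cat("  stop fraction:", object@stopFraction, "\n")
})

#' @rdname CorrelationGraph-class
#' @export
setMethod("interactionGraph", "CorrelationGraph", function(x) x@graph)

#' @rdname CorrelationGraph-class
#' @export
setMethod("graphEdges", "CorrelationGraph", function(x) {
  e <- igraph::as_data_frame(x@graph, what = "edges")
  names(e)[1:2] <- c("gene_a", "gene_b")
  e
})

setMethod("show", "CorrelationGraph", function(object) {
  cat("CorrelationGraph:", nrow(object@correlations), "genes,",
      igraph::ecount(object@graph), "edges at r >=", object@threshold, "\n")
})
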