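#' ScreenTensor: phenotype values of a template-query double-knockdown screen
#'
#' The central data container: a 5-dimensional numeric array of per-experiment
#' phenotype values indexed by (target gene, target dsRNA design, query gene,
#' query dsRNA design, feature). Each gene is silenced by two
#' sequence-independent dsRNA designs, so every gene pair is measured four
#' times (the 2 x 2 reagent grid).
#'
#' @slot values 5-D numeric array with complete dimnames; dims 2 and 4 have
#'   extent 2 (the two dsRNA designs per gene).
#' @slot transformed logical scalar; \code{TRUE} once the values are on the
#'   variance-stabilised scale.
#'
#' @param values,transformed see slot descriptions.
#' @param x a \code{ScreenTensor}.
#'
#' @examples
#' sim <- simulateScreen(simulationConfig(nTargets = 12, nQueries = 10,
#'                                        nFeatures = 4, seed = 1L))
#' sim$tensor
#' targetGenes(sim$tensor)[1:3]
#'
#' @aliases tensorValues targetGenes queryGenes featureNames isTransformed
#' @export ScreenTensor
#' @exportClass ScreenTensor
ScreenTensor <- setClass("ScreenTensor",
  slots = c(values = "array", transformed = "logical"),
  prototype = prototype(transformed = FALSE))

setValidity("ScreenTensor", function(object) {
  v <- object@values
  if (length(dim(v)) != 5L)
    return("'values' must be a 5-D array (target, target design, query, query design, feature)")
  if (!is.numeric(v))
    return("'values' must be numeric")
  if (dim(v)[2L] != 2L || dim(v)[4L] != 2L)
    return("design axes (dims 2 and 4) must have extent 2")
  dn <- dimnames(v)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
    return("all five axes must carry dimnames")
  if (anyDuplicated(dn[[1L]]) || anyDuplicated(dn[[3L]]) || anyDuplicated(dn[[5L]]))
    return("target, query and feature labels must be unique")
  if (length(object@transformed) != 1L || is.na(object@transformed))
    return("'transformed' must be TRUE or FALSE")
  TRUE
})

#' VstParams: per-feature cofactors of the variance-stabilising transformation
#'
#' Holds the cofactor lambda of the transformation
#' \eqn{g(x) = \mathrm{asinh}(x/\lambda_f)} for every feature. The cofactor is
#' on the scale of the raw feature values and must be strictly positive.
#'
#' @slot lambda strictly positive named numeric vector, one entry per feature.
#' @param lambda see slot description.
#' @param x a \code{VstParams}.
#' @aliases vstLambda
#' @seealso [estimateVstParams()]
#' @export VstParams
#' @exportClass VstParams
VstParams <- setClass("VstParams", slots = c(lambda = "numeric"))

setValidity("VstParams", function(object) {
  l <- object@lambda
  if (length(l) == 0L) return("'lambda' must contain at least one feature")
  if (is.null(names(l)) || anyDuplicated(names(l)) || any(!nzchar(names(l))))
    return("'lambda' must have unique non-empty feature names")
  if (any(!is.finite(l)) || any(l <= 0))
    return("all cofactors must be finite and strictly positive")
  TRUE
})

#' QcReport: reproducibility and reagent-concordance quality control
#'
#' Result of the two screen-level hard filters: per-feature Pearson
#' correlation between replicate measurements, and per-gene Pearson
#' correlation between the phenotypic profiles of the two dsRNA designs.
#' Both filters use strict inequalities: an entity passes only if its
#' correlation exceeds the threshold.
#'
#' @slot featureStats data.frame with columns \code{feature}, \code{r},
#'   \code{n}, \code{status} ("pass", "fail" or "insufficient").
#' @slot geneStats data.frame with columns \code{gene}, \code{r}, \code{n},
#'   \code{status}.
#' @slot featureThreshold,geneThreshold the thresholds used (NA when the
#'   corresponding filter was not run).
#' @param x a \code{QcReport}.
#' @aliases featureStats geneStats passingFeatures passingGenes
#' @export QcReport
#' @exportClass QcReport
QcReport <- setClass("QcReport",
  slots = c(featureStats = "data.frame", geneStats = "data.frame",
            featureThreshold = "numeric", geneThreshold = "numeric"),
  prototype = prototype(
    featureStats = data.frame(feature = character(), r = numeric(),
                              n = integer(), status = character()),
    geneStats = data.frame(gene = character(), r = numeric(),
                           n = integer(), status = character()),
    featureThreshold = NA_real_, geneThreshold = NA_real_))

setValidity("QcReport", function(object) {
  fs <- object@featureStats; gs <- object@geneStats
  if (!all(c("feature", "r", "n", "status") %in% names(fs)))
    return("featureStats must have columns feature, r, n, status")
  if (!all(c("gene", "r", "n", "status") %in% names(gs)))
    return("geneStats must have columns gene, r, n, status")
  rr <- c(fs$r, gs$r)
  if (any(!is.na(rr) & (rr < -1 | rr > 1)))
    return("correlations must lie in [-1, 1] or be missing")
  TRUE
})

#' MainEffects: additive decomposition of a transformed screen tensor
#'
#' Per-feature decomposition of the double-knockdown values into an
#' intercept, per-reagent target main effects, per-reagent query main
#' effects, and the interaction residuals (pi-scores), obtained by two-way
#' median polish. Effects are median-centred: the median over targets of
#' each (design, feature) slice of the target effects is zero, and likewise
#' for query effects.
#'
#' @slot intercept named numeric, one value per feature (averaged over the
#'   four design pairs).
#' @slot interceptByPair 2 x 2 x features array of per-design-pair
#'   intercepts.
#' @slot target targets x 2 x features array of target main effects.
#' @slot query queries x 2 x features array of query main effects.
#' @slot pi 5-D array of interaction residuals, same shape as the tensor the
#'   fit came from.
#' @slot flaggedTargets,flaggedQueries genes whose effects are unreliable
#'   because more than half of their values were missing.
#' @param x a \code{MainEffects}.
#' @aliases targetEffects queryEffects effectIntercept piScores
#' @seealso [fitMainEffects()]
#' @export MainEffects
#' @exportClass MainEffects
MainEffects <- setClass("MainEffects",
  slots = c(intercept = "numeric", interceptByPair = "array",
            target = "array", query = "array", pi = "array",
            flaggedTargets = "character", flaggedQueries = "character"))

setValidity("MainEffects", function(object) {
  if (length(dim(object@pi)) != 5L) return("'pi' must be a 5-D array")
  if (length(dim(object@target)) != 3L || length(dim(object@query)) != 3L)
    return("'target' and 'query' must be 3-D arrays (gene, design, feature)")
  nf <- dim(object@pi)[5L]
  if (length(object@intercept) != nf)
    return("'intercept' length must equal the number of features")
  TRUE
})

#' InteractionStats: gene-pair interaction summaries with moderated tests
#'
#' Per (target gene, query gene, feature): the mean pi-score over the up to
#' four dsRNA reagent pairs, the empirical-Bayes moderated t-statistic
#' against a zero mean, its two-sided p-value and the Benjamini-Hochberg
#' adjusted p-value (adjustment within each feature across all gene pairs).
#'
#' @slot table data.frame with columns \code{target}, \code{query},
#'   \code{feature}, \code{mean_pi}, \code{n}, \code{t}, \code{p},
#'   \code{p_adj}.
#' @slot priorDf named numeric: prior degrees of freedom d0 per feature.
#' @slot priorVar named numeric: prior variance s0^2 per feature.
#' @param x an \code{InteractionStats}.
#' @aliases interactionTable priorDf priorVar
#' @seealso [summarizeInteractions()]
#' @export InteractionStats
#' @exportClass InteractionStats
InteractionStats <- setClass("InteractionStats",
  slots = c(table = "data.frame", priorDf = "numeric", priorVar = "numeric"))

setValidity("InteractionStats", function(object) {
  tb <- object@table
  need <- c("target", "query", "feature", "mean_pi", "n", "t", "p", "p_adj")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  ok <- !is.na(tb$p) & !is.na(tb$p_adj)
  if (any(tb$p_adj[ok] < tb$p[ok] - 1e-12))
    return("adjusted p-values must not be smaller than raw p-values")
  if (any(ok & (tb$p < 0 | tb$p > 1 | tb$p_adj < 0 | tb$p_adj > 1)))
    return("p-values must lie in [0, 1]")
  if (any(!is.na(tb$n) & tb$n > 4))
    return("at most 4 reagent-pair measurements per gene pair")
  TRUE
})

#' FeatureSelectionResult: step-wise non-redundant phenotype selection
#'
#' Ordered record of the step-wise selection that starts from the three
#' seed phenotypes and adds, at each step, the candidate feature whose
#' regression residuals are most correlated between replicates. Selection
#' stops at the first step where the fraction of candidates with positive
#' residual correlation no longer exceeds the stop threshold.
#'
#' @slot seeds the seed features (carry no gain value).
#' @slot selected all retained features, seeds first, then in selection
#'   order.
#' @slot steps data.frame with columns \code{step}, \code{feature},
#'   \code{gain}, \code{positive_fraction}; the final row records the
#'   stopping step with \code{feature = NA}.
#' @slot stopFraction the stop threshold used.
#' @param x a \code{FeatureSelectionResult}.
#' @aliases selectedFeatures selectionSteps
#' @seealso [selectFeatures()]
#' @export FeatureSelectionResult
#' @exportClass FeatureSelectionResult
FeatureSelectionResult <- setClass("FeatureSelectionResult",
  slots = c(seeds = "character", selected = "character",
            steps = "data.frame", stopFraction = "numeric"))

setValidity("FeatureSelectionResult", function(object) {
  if (!all(object@seeds %in% object@selected))
    return("seeds must be part of the selected set")
  if (!all(c("step", "feature", "gain", "positive_fraction") %in%
           names(object@steps)))
    return("steps must have columns step, feature, gain, positive_fraction")
  TRUE
})

#' CorrelationGraph: interaction-profile correlation network
#'
#' Undirected network over target genes where an edge connects two genes
#' whose interaction profiles (pi-scores against all queries in all
#' features) have Pearson correlation greater than or equal to the
#' threshold (inclusive).
#'
#' @slot graph an \pkg{igraph} graph with edge attribute \code{r}.
#' @slot correlations symmetric gene x gene correlation matrix.
#' @slot threshold the edge threshold used.
#' @param x a \code{CorrelationGraph}.
#' @aliases interactionGraph graphEdges
#' @seealso [buildCorrelationGraph()]
#' @export CorrelationGraph
#' @exportClass CorrelationGraph
CorrelationGraph <- setClass("CorrelationGraph",
  slots = c(graph = "ANY", correlations = "matrix", threshold = "numeric"))

setValidity("CorrelationGraph", function(object) {
  R <- object@correlations
  if (nrow(R) != ncol(R)) return("correlation matrix must be square")
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8, check.attributes = FALSE)))
    return("correlation matrix must be symmetric")
  TRUE
})

#' SimulationConfig: study conditions for a synthetic combinatorial screen
#'
#' Defines the dimensions, effect sizes, planted-interaction structure,
#' noise level and reagent-defect rate of a simulated template-query
#' double-knockdown screen. The defaults describe the benchmark screen used
#' throughout the package: 50 targets x 12 queries, two dsRNA designs per
#' gene, 20 phenotypic features (three of them the seed phenotypes cell
#' number, mitotic index and cell area), 10\% interacting gene pairs of
#' which half are directional with coefficient magnitude 0.8, measurement
#' noise at 25\% of the main-effect standard deviation, and 6\% of targets
#' with a discordant second dsRNA design.
#'
#' @slot nTargets,nQueries,nFeatures screen dimensions (two designs per gene
#'   are implied).
#' @slot featureNames feature labels; the first three default to the seed
#'   phenotypes so that [selectFeatures()] defaults apply unmodified.
#' @slot effectSd standard deviation of single-gene main effects on the
#'   transformed scale (targets and queries alike).
#' @slot interactingFraction fraction of gene pairs with a planted
#'   interaction.
#' @slot directionalFraction fraction of interacting pairs that are
#'   directional rather than symmetric.
#' @slot directionCoef magnitude |c| of the directional coefficient; a
#'   directed pair's pi-vector is c times the downstream gene's effect
#'   vector.
#' @slot alleviatingFraction fraction of directional pairs with c < 0
#'   (alleviating).
#' @slot symmetricPiSd per-feature SD of the isotropic pi-scores of
#'   symmetric interacting pairs.
#' @slot noiseSd SD of the i.i.d. measurement noise on the transformed
#'   scale.
#' @slot discordantFraction fraction of targets whose second dsRNA design is
#'   off-target (receives large additive deviations on a random half of the
#'   features).
#' @slot discordantShiftSd SD of those additive reagent deviations.
#' @slot nComplexes,complexSize number and size of planted "complexes":
#'   groups of targets sharing one interaction profile (for network
#'   recovery studies; 0 disables them).
#' @slot complexPiSd per-feature SD of a complex's shared profile.
#' @slot lambda VST cofactor(s) used to emit raw-scale values (recycled over
#'   features).
#' @slot seed integer random seed; the whole screen is reproducible from it.
#' @param x a \code{SimulationConfig}.
#' @seealso [simulationConfig()], [simulateScreen()]
#' @export
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(nTargets = "integer", nQueries = "integer", nFeatures = "integer",
            featureNames = "character", effectSd = "numeric",
            interactingFraction = "numeric", directionalFraction = "numeric",
            directionCoef = "numeric", alleviatingFraction = "numeric",
            symmetricPiSd = "numeric", noiseSd = "numeric",
            discordantFraction = "numeric", discordantShiftSd = "numeric",
            nComplexes = "integer", complexSize = "integer",
            complexPiSd = "numeric", lambda = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  frac <- c(object@interactingFraction, object@directionalFraction,
            object@alleviatingFraction, object@discordantFraction)
  if (any(frac < 0 | frac > 1)) return("all fractions must lie in [0, 1]")
  if (object@nTargets < 10L || object@nQueries < 10L)
    return("at least 10 targets and 10 queries are required for stable scoring")
  if (object@nFeatures < 1L) return("at least one feature is required")
  if (length(object@featureNames) != object@nFeatures ||
      anyDuplicated(object@featureNames))
    return("featureNames must be unique and match nFeatures")
  if (any(object@lambda <= 0)) return("VST cofactors must be positive")
  if (object@noiseSd < 0 || object@effectSd <= 0)
    return("effectSd must be positive and noiseSd non-negative")
  if (object@nComplexes > 0L &&
      object@nComplexes * object@complexSize > object@nTargets)
    return("planted complexes cannot exceed the number of targets")
  TRUE
})
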