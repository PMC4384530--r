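#' @include AllClasses.R AllGenerics.R
NULL

.defaultPipelineConfig <- function() {
  list(
    feature_threshold = 0.6,   # replicate reproducibility (strict >)
    gene_threshold = 0.7,      # between-design concordance (strict >)
    fdr = 0.01,                # interaction significance
    edge_threshold = 0.6,      # profile-correlation edges (inclusive >=)
    q_low = 0.10, q_high = 0.95,  # direction-call quantiles
    stop_fraction = 0.5,       # feature-selection stop criterion
    seed_features = c("cell_number", "mitotic_index", "cell_area"),
    seed = 1L)
}

.validatePipelineConfig <- function(config) {
  def <- .defaultPipelineConfig()
  unknown <- setdiff(names(config),
                     c(names(def), "input", "simulate", "select_features"))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  config <- utils::modifyList(def, config)
  with(config, {
    stopifnot(feature_threshold >= -1, feature_threshold <= 1,
              gene_threshold >= -1, gene_threshold <= 1,
              fdr > 0, fdr < 1, edge_threshold >= -1, edge_threshold <= 1,
              stop_fraction >= 0, stop_fraction <= 1)
    if (q_low >= q_high)
      stop("q_low must be smaller than q_high")
  })
  config
}

#' Run the full screen-analysis pipeline
#'
#' Orchestrates simulate (or load) -> variance-stabilising transform ->
#' quality control -> feature selection -> main effects and pi-scores ->
#' moderated interaction tests -> directional calls -> profile-correlation
#' network, writing every intermediate artefact as TSV/GraphML into
#' \code{outDir} together with a run manifest (configuration, configuration
#' checksum, package version, seed). Stages communicate only through the
#' returned objects and the serialised artefacts, so a rerun with an
#' identical configuration reproduces identical outputs.
#'
#' @param config either a path to a YAML file or a named list. Recognised
#'   keys (defaults in parentheses): \code{feature_threshold} (0.6),
#'   \code{gene_threshold} (0.7), \code{fdr} (0.01), \code{edge_threshold}
#'   (0.6), \code{q_low} (0.10), \code{q_high} (0.95), \code{stop_fraction}
#'   (0.5), \code{seed_features}, \code{seed} (1), and either \code{input}
#'   (path to a long-format raw tensor TSV) or \code{simulate} (a list of
#'   [simulationConfig()] arguments). \code{select_features} (TRUE) may be
#'   set to FALSE to keep all features.
#' @param outDir output directory, created if needed.
#' @param verbose log stage progress to stderr.
#' @return (invisibly) a list with all stage results: \code{vst},
#'   \code{qc}, \code{selection}, \code{effects}, \code{stats},
#'   \code{fits}, \code{thresholds}, \code{calls}, \code{graph},
#'   \code{truth} (when simulated), \code{manifest}.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("episcan_run_"),
                        verbose = TRUE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- .validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[episcan] ", ...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  truth <- NULL; singles <- NULL
  if (!is.null(config$input)) {
    raw <- stage("load", readScreenTensor(config$input))
  } else {
    simArgs <- if (is.list(config$simulate)) config$simulate else list()
    if (is.null(simArgs$seed)) simArgs$seed <- config$seed
    sim <- stage("simulate", simulateScreen(do.call(simulationConfig,
                                                    simArgs)))
    raw <- sim$tensor; truth <- sim$truth; singles <- sim$singles
    writeScreenTensor(raw, file.path(outDir, "raw_tensor.tsv"))
  }

  vst <- stage("transform", estimateVstParams(raw))
  writeVstParams(vst, file.path(outDir, "vst_params.tsv"))
  tensor <- applyVst(raw, vst)

  selection <- NULL
  features <- featureNames(tensor)
  doSelect <- !identical(config$select_features, FALSE) && !is.null(singles)
  if (doSelect) {
    selection <- stage("select-features", {
      s1 <- applyVst(singles[[1L]], vst); s2 <- applyVst(singles[[2L]], vst)
      selectFeatures(s1, s2, seeds = config$seed_features,
                     stopFraction = config$stop_fraction,
                     reproducibilityThreshold = config$feature_threshold)
    })
    writeFeatureSelection(selection, file.path(outDir,
                                               "feature_selection.tsv"))
    features <- selectedFeatures(selection)
  }

  qc <- stage("qc", reagentConcordance(tensor, features = features,
                                       threshold = config$gene_threshold))
  writeQcReport(qc, file.path(outDir, "qc_report.tsv"))
  keep <- QcReport(geneStats = geneStats(qc),
                   featureStats = data.frame(
                     feature = featureNames(tensor),
                     r = NA_real_, n = NA_integer_,
                     status = ifelse(featureNames(tensor) %in% features,
                                     "pass", "fail")),
                   geneThreshold = config$gene_threshold,
                   featureThreshold = config$feature_threshold)
  filtered <- stage("filter", filterScreen(tensor, keep))

  effects <- stage("score", fitMainEffects(filtered))
  stats <- summarizeInteractions(effects)
  writeInteractionStats(stats, file.path(outDir, "interaction_stats.tsv"))

  fits <- stage("direction", fitDirectionModels(effects, stats,
                                                fdr = config$fdr))
  thresholds <- deriveThresholds(fits, qLow = config$q_low,
                                 qHigh = config$q_high)
  calls <- callDirections(fits, thresholds)
  writeDirectionCalls(calls, file.path(outDir, "direction_calls.tsv"))
  if (nrow(calls))
    writeDirectionGraphML(calls, file.path(outDir, "direction_graph.graphml"))

  graph <- stage("network", {
    prof <- buildProfileMatrix(effects)
    buildCorrelationGraph(prof, threshold = config$edge_threshold)
  })
  writeEdgeList(graph, file.path(outDir, "correlation_edges.tsv"))
  writeGraphML(graph, file.path(outDir, "correlation_graph.graphml"))

  configPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(config, configPath)
  manifest <- list(
    package = "episcan",
    version = as.character(utils::packageVersion("episcan")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(configPath)),
    n_targets = length(targetGenes(filtered)),
    n_queries = length(queryGenes(filtered)),
    n_features = length(featureNames(filtered)),
    n_direction_calls = nrow(calls))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  say("done: ", outDir)
  invisible(list(vst = vst, qc = qc, selection = selection,
                 effects = effects, stats = stats, fits = fits,
                 thresholds = thresholds, calls = calls, graph = graph,
                 truth = truth, manifest = manifest, outDir = outDir))
}

#' Counts implied by a template-query screen design
#'
#' Pure design arithmetic: the number of tested gene-pair combinations and
#' the number of measurements per pair implied by the screen dimensions and
#' the number of sequence-independent dsRNA designs per gene.
#'
#' @param nTargets,nQueries numbers of target and query genes.
#' @param nDesigns dsRNA designs per gene (default 2).
#' @return list with \code{pairs} and \code{measurementsPerPair}.
#' @examples
#' screenDesign(1367, 72)   # 98424 tested pairs, 4 measurements each
#' @export
screenDesign <- function(nTargets, nQueries, nDesigns = 2L) {
  stopifnot(nTargets > 0, nQueries > 0, nDesigns > 0)
  list(pairs = nTargets * nQueries,
       measurementsPerPair = nDesigns * nDesigns)
}
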