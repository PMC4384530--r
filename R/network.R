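#' @include AllClasses.R AllGenerics.R
NULL

#' Build the gene-level interaction-profile matrix
#'
#' One row per target gene; columns are all (query, feature) combinations;
#' entries are the mean pi-score over the up to four dsRNA reagent pairs.
#' Where a target gene also appears as a query, its self-pair columns are
#' set to missing so they never contribute to profile correlations.
#'
#' @param x a \linkS4class{MainEffects} object or a 5-D pi-score array.
#' @return targets x (queries * features) numeric matrix; column names are
#'   \code{"query:feature"}.
#' @export
buildProfileMatrix <- function(x) {
  pi <- if (is(x, "MainEffects")) x@pi else x
  stopifnot(is.array(pi), length(dim(pi)) == 5L)
  d <- dim(pi); dn <- dimnames(pi)
  ## mean over the two design axes -> targets x queries x features
  mp <- apply(pi, c(1L, 3L, 5L), mean, na.rm = TRUE)
  mp[is.nan(mp)] <- NA_real_
  prof <- matrix(mp, nrow = d[1L], ncol = d[3L] * d[5L],
                 dimnames = list(dn[[1L]],
                                 paste(rep(dn[[3L]], times = d[5L]),
                                       rep(dn[[5L]], each = d[3L]),
                                       sep = ":")))
  self <- intersect(dn[[1L]], dn[[3L]])
  for (g in self)
    prof[g, paste(g, dn[[5L]], sep = ":")] <- NA_real_
  prof
}

#' Build the interaction-profile correlation network
#'
#' Pearson correlation between the interaction profiles of every pair of
#' genes, on pairwise-complete columns; an undirected edge is drawn for
#' every pair with correlation greater than or equal to the threshold
#' (inclusive). Gene pairs sharing fewer than \code{minShared} complete
#' columns get no correlation (the genes may end up isolated, with a
#' warning).
#'
#' @param profiles matrix from [buildProfileMatrix()].
#' @param threshold edge threshold (default 0.6, inclusive).
#' @param minShared minimum number of shared complete columns per gene pair
#'   (default 3).
#' @return a \linkS4class{CorrelationGraph}.
#' @export
buildCorrelationGraph <- function(profiles, threshold = 0.6, minShared = 3L) {
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)))
  x <- t(profiles)
  R <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  ok <- is.finite(x) * 1
  shared <- t(ok) %*% ok
  low <- shared < minShared
  if (any(low[upper.tri(low)])) {
    R[low] <- NA_real_
    warning("some gene pairs share fewer than ", minShared,
            " complete profile columns; their correlations are undefined")
  }
  diag(R) <- 1
  idx <- which(upper.tri(R) & !is.na(R) & R >= threshold, arr.ind = TRUE)
  edges <- data.frame(gene_a = rownames(R)[idx[, 1L]],
                      gene_b = rownames(R)[idx[, 2L]],
                      r = R[idx])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = rownames(profiles))
  CorrelationGraph(graph = g, correlations = R, threshold = threshold)
}

#' Connected components of a correlation network
#'
#' @param x a \linkS4class{CorrelationGraph}.
#' @return named integer vector of component memberships (one per gene).
#' @export
graphComponents <- function(x) {
  stopifnot(is(x, "CorrelationGraph"))
  igraph::components(x@graph)$membership
}

#' Export a correlation network
#'
#' \code{writeEdgeList} writes the 3-column edge list (gene_a, gene_b, r) as
#' TSV; \code{writeGraphML} writes GraphML with the correlation as an edge
#' attribute (optionally with node annotation columns).
#'
#' @param x a \linkS4class{CorrelationGraph}.
#' @param path file path.
#' @param nodeAttributes optional data.frame of node annotations whose first
#'   column holds the gene names.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(x, path) {
  stopifnot(is(x, "CorrelationGraph"))
  utils::write.table(graphEdges(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
writeGraphML <- function(x, path, nodeAttributes = NULL) {
  stopifnot(is(x, "CorrelationGraph"))
  g <- x@graph
  if (!is.null(nodeAttributes)) {
    idx <- match(igraph::V(g)$name, nodeAttributes[[1L]])
    for (col in names(nodeAttributes)[-1L])
      g <- igraph::set_vertex_attr(g, col, value = nodeAttributes[[col]][idx])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Rand index between two partitions
#'
#' Pair-counting agreement between two labelled partitions of the same
#' items: the fraction of item pairs on which the partitions agree (placed
#' together in both, or apart in both).
#'
#' @param labels1,labels2 equal-length partition label vectors.
#' @return the Rand index in [0, 1].
#' @export
randIndex <- function(labels1, labels2) {
  stopifnot(length(labels1) == length(labels2), length(labels1) >= 2L)
  n <- length(labels1)
  same1 <- outer(labels1, labels1, "==")
  same2 <- outer(labels2, labels2, "==")
  up <- upper.tri(same1)
  mean(same1[up] == same2[up])
}
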