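#' @include AllClasses.R AllGenerics.R
NULL

.pairCor <- function(v1, v2, minPairs, minCompleteFraction = 0) {
  ok <- is.finite(v1) & is.finite(v2)
  n <- sum(ok)
  if (n < minPairs || n < minCompleteFraction * length(v1) ||
      stats::sd(v1[ok]) == 0 || stats::sd(v2[ok]) == 0)
    return(list(r = NA_real_, n = n, status = "insufficient"))
  list(r = stats::cor(v1[ok], v2[ok]), n = n, status = "ok")
}

#' Replicate reproducibility of phenotypic features
#'
#' Computes, for every feature, the Pearson correlation of its values across
#' experiments between two replicate measurements, and flags features whose
#' correlation exceeds the threshold (strictly) as reproducible. Features with
#' fewer than three complete pairs are flagged \code{"insufficient"} rather
#' than pass/fail.
#'
#' @param rep1,rep2 experiments x features matrices of replicate measurements
#'   with identical dimnames.
#' @param threshold reproducibility threshold on the Pearson correlation;
#'   default 0.6, with strict inequality (r = 0.6 exactly fails).
#' @return a \linkS4class{QcReport} with the feature part filled in.
#' @examples
#' sim <- simulateScreen(simulationConfig(nTargets = 12, nQueries = 10,
#'                                        nFeatures = 4, seed = 1L))
#' featureReproducibility(sim$singles[[1]], sim$singles[[2]])
#' @export
featureReproducibility <- function(rep1, rep2, threshold = 0.6) {
  stopifnot(is.matrix(rep1), is.matrix(rep2),
            identical(colnames(rep1), colnames(rep2)),
            nrow(rep1) == nrow(rep2))
  feats <- colnames(rep1)
  rows <- lapply(feats, function(f) {
    cc <- .pairCor(rep1[, f], rep2[, f], minPairs = 3L)
    status <- if (cc$status == "insufficient") "insufficient"
              else if (cc$r > threshold) "pass" else "fail"
    data.frame(feature = f, r = cc$r, n = cc$n, status = status)
  })
  QcReport(featureStats = do.call(rbind, rows), featureThreshold = threshold)
}

#' On-target concordance between the two dsRNA designs of each target gene
#'
#' For every target gene, correlates the flattened phenotypic profile of its
#' first dsRNA design with that of its second design, across all query
#' reagents and the given features. Genes whose between-design Pearson r
#' exceeds the threshold (strictly) pass; genes with a missing design or
#' fewer than half of the profile entries complete are flagged
#' \code{"insufficient"}.
#'
#' Profiles are built on per-feature standardised values (each feature
#' centred and scaled by its screen-wide mean and SD) so that features with
#' different scales and offsets contribute comparably; otherwise the
#' between-feature spread, which is common to both designs, would dominate
#' the correlation.
#'
#' @param tensor a \linkS4class{ScreenTensor} (transformed scale recommended).
#' @param features features over which to build the profiles; default all.
#' @param threshold concordance threshold; default 0.7, strict inequality.
#' @return a \linkS4class{QcReport} with the gene part filled in.
#' @export
reagentConcordance <- function(tensor, features = NULL, threshold = 0.7) {
  stopifnot(is(tensor, "ScreenTensor"))
  v <- tensor@values
  if (is.null(features)) features <- dimnames(v)[[5L]]
  stopifnot(all(features %in% dimnames(v)[[5L]]))
  for (f in features) {
    sl <- v[, , , , f]
    mu <- mean(sl, na.rm = TRUE)
    sg <- stats::sd(sl, na.rm = TRUE)
    if (!is.finite(sg) || sg == 0) sg <- 1
    v[, , , , f] <- (sl - mu) / sg
  }
  rows <- lapply(dimnames(v)[[1L]], function(g) {
    v1 <- as.vector(v[g, 1L, , , features])
    v2 <- as.vector(v[g, 2L, , , features])
    cc <- .pairCor(v1, v2, minPairs = 3L, minCompleteFraction = 0.5)
    status <- if (cc$status == "insufficient") "insufficient"
              else if (cc$r > threshold) "pass" else "fail"
    data.frame(gene = g, r = cc$r, n = cc$n, status = status)
  })
  QcReport(geneStats = do.call(rbind, rows), geneThreshold = threshold)
}

#' Restrict a screen tensor to QC-passing genes and features
#'
#' Drops target genes and features that did not pass the corresponding filter
#' in the report (entities flagged \code{"insufficient"} are also dropped).
#' Entities absent from the report are retained, which makes filtering
#' idempotent; retained values are never altered.
#'
#' @param tensor a \linkS4class{ScreenTensor}.
#' @param report a \linkS4class{QcReport} computed on the same axes.
#' @return the filtered \linkS4class{ScreenTensor}.
#' @export
filterScreen <- function(tensor, report) {
  stopifnot(is(tensor, "ScreenTensor"), is(report, "QcReport"))
  v <- tensor@values
  keepT <- dimnames(v)[[1L]]
  keepF <- dimnames(v)[[5L]]
  gs <- report@geneStats
  if (nrow(gs)) {
    dropG <- gs$gene[gs$status != "pass"]
    keepT <- setdiff(keepT, dropG)
  }
  fs <- report@featureStats
  if (nrow(fs)) {
    dropF <- fs$feature[fs$status != "pass"]
    keepF <- setdiff(keepF, dropF)
  }
  if (!length(keepT) || !length(keepF))
    stop("all entries filtered")
  ScreenTensor(values = v[keepT, , , , keepF, drop = FALSE],
               transformed = tensor@transformed)
}

#' Export a QC report as TSV
#'
#' Long format with columns entity, statistic, value, pass.
#'
#' @param report a \linkS4class{QcReport}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeQcReport <- function(report, path) {
  stopifnot(is(report, "QcReport"))
  fs <- report@featureStats; gs <- report@geneStats
  out <- rbind(
    if (nrow(fs)) data.frame(entity = fs$feature,
                             statistic = "replicate_correlation",
                             value = fs$r, pass = fs$status),
    if (nrow(gs)) data.frame(entity = gs$gene,
                             statistic = "design_concordance",
                             value = gs$r, pass = gs$status))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
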