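#' @include AllClasses.R AllGenerics.R
NULL

.replicateResiduals <- function(mat, candidate, selected) {
  y <- mat[, candidate]
  X <- cbind(`(Intercept)` = 1, mat[, selected, drop = FALSE])
  fit <- stats::lm.fit(X, y)
  list(residuals = fit$residuals, deficient = fit$rank < ncol(X))
}

#' Information gain of a candidate phenotype feature
#'
#' Fits, independently within each replicate, a linear regression of the
#' candidate feature on the already selected features over all experiments;
#' the gain is the Pearson correlation between the two replicates' residual
#' vectors. Residual correlation close to zero means the candidate carries no
#' reproducible information beyond the selected set.
#'
#' @param candidate feature name, not in \code{selected}.
#' @param selected character vector of already selected features (may be
#'   empty, in which case residuals are the centred values).
#' @param rep1,rep2 experiments x features replicate matrices with identical
#'   dimnames.
#' @return the gain, a correlation in [-1, 1]; attribute \code{"flagged"} is
#'   \code{TRUE} when the regression design was rank deficient (the gain is
#'   then computed from the pivoted least-squares fit).
#' @export
residualGain <- function(candidate, selected, rep1, rep2) {
  stopifnot(identical(colnames(rep1), colnames(rep2)),
            candidate %in% colnames(rep1),
            !candidate %in% selected,
            all(selected %in% colnames(rep1)))
  if (nrow(rep1) < length(selected) + 2L)
    stop("need at least |selected| + 2 experiments")
  r1 <- .replicateResiduals(rep1, candidate, selected)
  r2 <- .replicateResiduals(rep2, candidate, selected)
  gain <- if (stats::sd(r1$residuals) == 0 || stats::sd(r2$residuals) == 0)
    0 else stats::cor(r1$residuals, r2$residuals)
  attr(gain, "flagged") <- r1$deficient || r2$deficient
  gain
}

#' Step-wise selection of a non-redundant phenotype subset
#'
#' Starting from the seed phenotypes (by default cell number, mitotic index
#' and cell area), repeatedly evaluates the residual-correlation gain of
#' every remaining candidate feature and adds the candidate with the maximum
#' gain. At each step the fraction of candidates with positive gain is
#' computed first; the iteration stops as soon as that fraction no longer
#' exceeds \code{stopFraction} (for uninformative candidates the expected
#' fraction is 0.5, so selection on pure noise terminates immediately).
#' Candidates whose replicate correlation does not exceed
#' \code{reproducibilityThreshold} are excluded before selection begins.
#'
#' Ties on the maximum gain are broken towards the lexicographically smaller
#' feature name, which makes the result invariant to the column order of the
#' input.
#'
#' @param rep1,rep2 experiments x features replicate matrices with identical
#'   dimnames.
#' @param seeds seed features; must be present in the data.
#' @param stopFraction stop threshold on the positive-gain fraction
#'   (default 0.5).
#' @param reproducibilityThreshold candidates at or below this replicate
#'   correlation are not considered (default 0.6; set to \code{-Inf} to keep
#'   all). Seeds are kept regardless.
#' @return a \linkS4class{FeatureSelectionResult}.
#' @examples
#' sim <- simulateReplicateFeatures(nExperiments = 200, nFactors = 2,
#'                                  nNoise = 4, seed = 1L)
#' selectFeatures(sim$rep1, sim$rep2)
#' @export
selectFeatures <- function(rep1, rep2,
                           seeds = c("cell_number", "mitotic_index",
                                     "cell_area"),
                           stopFraction = 0.5,
                           reproducibilityThreshold = 0.6) {
  stopifnot(identical(colnames(rep1), colnames(rep2)))
  if (!all(seeds %in% colnames(rep1)))
    stop("seed feature(s) missing from data: ",
         paste(setdiff(seeds, colnames(rep1)), collapse = ", "))
  candidates <- sort(setdiff(colnames(rep1), seeds))
  if (is.finite(reproducibilityThreshold) && length(candidates)) {
    repro <- vapply(candidates, function(f) {
      cc <- .pairCor(rep1[, f], rep2[, f], minPairs = 3L)
      if (is.na(cc$r)) -Inf else cc$r
    }, numeric(1))
    candidates <- candidates[repro > reproducibilityThreshold]
  }
  selected <- seeds
  steps <- data.frame(step = integer(), feature = character(),
                      gain = numeric(), positive_fraction = numeric())
  step <- 0L
  while (length(candidates)) {
    step <- step + 1L
    gains <- vapply(candidates,
                    function(f) as.numeric(residualGain(f, selected,
                                                        rep1, rep2)),
                    numeric(1))
    posFrac <- mean(gains > 0)
    if (posFrac <= stopFraction) {
      steps <- rbind(steps, data.frame(step = step, feature = NA_character_,
                                       gain = NA_real_,
                                       positive_fraction = posFrac))
      break
    }
    best <- candidates[gains == max(gains)][1L]  # candidates are sorted
    steps <- rbind(steps, data.frame(step = step, feature = best,
                                     gain = gains[[best]],
                                     positive_fraction = posFrac))
    selected <- c(selected, best)
    candidates <- setdiff(candidates, best)
  }
  FeatureSelectionResult(seeds = seeds, selected = selected, steps = steps,
                         stopFraction = stopFraction)
}

#' Greedy query-panel selection by explained variance
#'
#' Orders the columns (queries) of an interaction-profile matrix by their
#' ability to explain the rest of the matrix: at each step the query is added
#' whose inclusion maximises the fraction of total matrix variance explained
#' by regressing every other column on the selected columns (intercept
#' included; selected columns count as fully explained, which makes the
#' explained-variance curve monotone non-decreasing and equal to 1 at the
#' full panel). Missing values are imputed by column means before selection.
#'
#' @param mat targets x queries interaction-profile matrix with column
#'   names.
#' @param k panel size to select (defaults to all queries).
#' @return data.frame with columns \code{size}, \code{query},
#'   \code{explained_variance} (cumulative).
#' @export
selectQueryPanel <- function(mat, k = ncol(mat)) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  if (k > ncol(mat)) stop("k exceeds the number of queries")
  for (j in seq_len(ncol(mat))) {
    miss <- !is.finite(mat[, j])
    if (any(miss)) mat[miss, j] <- mean(mat[!miss, j])
  }
  sst <- sum(scale(mat, scale = FALSE)^2)
  if (sst == 0) stop("matrix has zero variance")
  evOf <- function(sel) {
    rest <- setdiff(colnames(mat), sel)
    if (!length(rest)) return(1)
    X <- cbind(1, mat[, sel, drop = FALSE])
    res <- stats::lm.fit(X, mat[, rest, drop = FALSE])$residuals
    1 - sum(res^2) / sst
  }
  sel <- character()
  out <- data.frame(size = integer(), query = character(),
                    explained_variance = numeric())
  for (size in seq_len(k)) {
    cand <- sort(setdiff(colnames(mat), sel))
    evs <- vapply(cand, function(q) evOf(c(sel, q)), numeric(1))
    best <- cand[evs == max(evs)][1L]
    sel <- c(sel, best)
    out <- rbind(out, data.frame(size = size, query = best,
                                 explained_variance = max(evs)))
  }
  out
}

#' Export a feature-selection result as TSV
#'
#' @param result a \linkS4class{FeatureSelectionResult}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureSelection <- function(result, path) {
  stopifnot(is(result, "FeatureSelectionResult"))
  seedRows <- data.frame(step = 0L, feature = result@seeds, gain = NA_real_,
                         positive_fraction = NA_real_)
  utils::write.table(rbind(seedRows, result@steps), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
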