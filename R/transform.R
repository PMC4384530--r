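#' @include AllClasses.R AllGenerics.R
NULL

## g(x) = asinh(x / lambda): linear with slope 1/lambda around 0,
## g(x) - log(x) -> log(2/lambda) for x >> lambda, and g(0) = 0.
## Non-finite inputs are carried through as NA (never dropped).
.vstForward <- function(x, lambda) {
  x[!is.finite(x)] <- NA_real_
  asinh(x / lambda)
}

.vstBackward <- function(y, lambda) {
  y[!is.finite(y)] <- NA_real_
  out <- lambda * sinh(y)
  if (any(is.infinite(out) & is.finite(y)))
    stop("numeric overflow while inverting the transformation")
  out
}

.scoreLambda <- function(x1, x2, lambda) {
  g1 <- .vstForward(x1, lambda)
  g2 <- .vstForward(x2, lambda)
  d <- abs(g1 - g2)
  m <- (g1 + g2) / 2
  ok <- is.finite(d) & is.finite(m)
  if (sum(ok) < 3L || stats::sd(d[ok]) == 0 || stats::sd(m[ok]) == 0)
    return(NA_real_)
  abs(stats::cor(d[ok], m[ok], method = "spearman"))
}

#' Estimate per-feature cofactors of the variance-stabilising transformation
#'
#' For each feature, picks the cofactor lambda of
#' \eqn{g(x) = \mathrm{asinh}(x/\lambda)} that makes the spread of paired
#' replicate differences as independent of the replicate mean as achievable:
#' lambda is chosen over a logarithmic grid to minimise the absolute Spearman
#' correlation between |difference| and mean of the transformed pair. With
#' purely multiplicative noise this drives the selected lambda into the
#' near-logarithmic regime; with additive constant-variance noise it selects a
#' large lambda so that the transform is near-linear over the data range.
#'
#' @param x paired observations: either a pair of experiments x features
#'   matrices (replicates, or the two dsRNA designs), given as a list of two
#'   matrices with identical dimnames, or a \linkS4class{ScreenTensor} whose
#'   two target designs are used as the pairing.
#' @param gridSize number of candidate cofactors.
#' @param gridRange multiplicative range of the candidate grid around the
#'   per-feature median absolute value.
#' @return a \linkS4class{VstParams} object.
#' @details Features whose values are all identical carry no information about
#'   the noise-mean relationship and raise an error naming the feature.
#' @examples
#' sim <- simulateScreen(simulationConfig(nTargets = 12, nQueries = 10,
#'                                        nFeatures = 4, seed = 1L))
#' estimateVstParams(sim$tensor)
#' @export
estimateVstParams <- function(x, gridSize = 50L, gridRange = c(1e-3, 1e3)) {
  if (is(x, "ScreenTensor")) {
    v <- x@values
    feats <- dimnames(v)[[5L]]
    pairs <- lapply(feats, function(f) {
      cbind(as.vector(v[, 1L, , , f]), as.vector(v[, 2L, , , f]))
    })
    names(pairs) <- feats
  } else if (is.list(x) && length(x) == 2L && is.matrix(x[[1L]])) {
    stopifnot(identical(dimnames(x[[1L]]), dimnames(x[[2L]])))
    feats <- colnames(x[[1L]])
    pairs <- lapply(feats, function(f) cbind(x[[1L]][, f], x[[2L]][, f]))
    names(pairs) <- feats
  } else {
    stop("'x' must be a ScreenTensor or a list of two replicate matrices")
  }
  if (any(gridRange <= 0) || gridSize < 2L)
    stop("candidate cofactor grid must be positive with at least 2 points")
  lambda <- vapply(feats, function(f) {
    p <- pairs[[f]]
    ok <- stats::complete.cases(p)
    if (sum(ok) < 2L)
      stop("feature '", f, "' has fewer than 2 complete observation pairs")
    p <- p[ok, , drop = FALSE]
    vals <- as.vector(p)
    if (diff(range(vals)) == 0)
      stop("feature '", f, "' has zero spread (all values identical)")
    centre <- stats::median(abs(vals))
    if (centre == 0) centre <- mean(abs(vals))
    grid <- exp(seq(log(gridRange[1L] * centre), log(gridRange[2L] * centre),
                    length.out = gridSize))
    scores <- vapply(grid, function(l) .scoreLambda(p[, 1L], p[, 2L], l),
                     numeric(1))
    if (all(is.na(scores)))
      stop("feature '", f, "' has zero replicate-difference spread")
    grid[which.min(scores)]
  }, numeric(1))
  VstParams(lambda = lambda)
}

.checkFeatures <- function(params, feats) {
  missing <- setdiff(feats, names(params@lambda))
  if (length(missing))
    stop("no transformation parameter for feature(s): ",
         paste(missing, collapse = ", "))
}

#' @rdname applyVst
#' @export
setMethod("applyVst", signature("ScreenTensor", "VstParams"),
  function(x, params, ...) {
    feats <- dimnames(x@values)[[5L]]
    .checkFeatures(params, feats)
    v <- x@values
    for (f in feats)
      v[, , , , f] <- .vstForward(v[, , , , f], params@lambda[[f]])
    ScreenTensor(values = v, transformed = TRUE)
  })

#' @rdname applyVst
#' @export
setMethod("applyVst", signature("matrix", "VstParams"),
  function(x, params, ...) {
    if (is.null(colnames(x))) stop("matrix columns must be named by feature")
    .checkFeatures(params, colnames(x))
    for (f in colnames(x)) x[, f] <- .vstForward(x[, f], params@lambda[[f]])
    x
  })

#' @rdname applyVst
#' @param feature for the numeric method: the feature whose cofactor applies.
#' @export
setMethod("applyVst", signature("numeric", "VstParams"),
  function(x, params, feature, ...) {
    .checkFeatures(params, feature)
    .vstForward(x, params@lambda[[feature]])
  })

#' @rdname inverseVst
#' @export
setMethod("inverseVst", signature("ScreenTensor", "VstParams"),
  function(x, params, ...) {
    feats <- dimnames(x@values)[[5L]]
    .checkFeatures(params, feats)
    v <- x@values
    for (f in feats)
      v[, , , , f] <- .vstBackward(v[, , , , f], params@lambda[[f]])
    ScreenTensor(values = v, transformed = FALSE)
  })

#' @rdname inverseVst
#' @export
setMethod("inverseVst", signature("matrix", "VstParams"),
  function(x, params, ...) {
    if (is.null(colnames(x))) stop("matrix columns must be named by feature")
    .checkFeatures(params, colnames(x))
    for (f in colnames(x)) x[, f] <- .vstBackward(x[, f], params@lambda[[f]])
    x
  })

#' @rdname inverseVst
#' @param feature for the numeric method: the feature whose cofactor applies.
#' @export
setMethod("inverseVst", signature("numeric", "VstParams"),
  function(x, params, feature, ...) {
    .checkFeatures(params, feature)
    .vstBackward(x, params@lambda[[feature]])
  })

#' Read or write transformation parameters as TSV
#'
#' Two-column tab-separated serialisation (feature, lambda).
#'
#' @param params a \linkS4class{VstParams}.
#' @param path file path.
#' @return \code{readVstParams} returns a \linkS4class{VstParams};
#'   \code{writeVstParams} returns \code{path} invisibly.
#' @export
writeVstParams <- function(params, path) {
  stopifnot(is(params, "VstParams"))
  utils::write.table(
    data.frame(feature = names(params@lambda), lambda = params@lambda),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVstParams
#' @export
readVstParams <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  VstParams(lambda = stats::setNames(tb$lambda, tb$feature))
}
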