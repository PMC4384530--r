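#' @include AllClasses.R AllGenerics.R
NULL

## median polish plus explicit final centring sweeps: medpolish() stops on a
## relative change criterion that can stall at floating-point level, so the
## row/col medians of its residuals are swept out until they vanish
## (< ~1e-12), which the downstream pi-score invariants rely on.
.polishMatrix <- function(m, eps, maxIter) {
  mp <- withCallingHandlers(
    stats::medpolish(m, eps = eps, maxiter = maxIter, trace.iter = FALSE,
                     na.rm = TRUE),
    warning = function(w) {
      if (grepl("did not converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  for (k in seq_len(50L)) {
    rm <- apply(mp$residuals, 1L, stats::median, na.rm = TRUE)
    rm[!is.finite(rm)] <- 0
    mp$residuals <- sweep(mp$residuals, 1L, rm)
    mp$row <- mp$row + rm
    cm <- apply(mp$residuals, 2L, stats::median, na.rm = TRUE)
    cm[!is.finite(cm)] <- 0
    mp$residuals <- sweep(mp$residuals, 2L, cm)
    mp$col <- mp$col + cm
    if (max(abs(rm), abs(cm)) < 1e-12) break
  }
  mp
}

#' Fit main effects and interaction residuals by two-way median polish
#'
#' Under the multiplicative model, double-knockdown values on the
#' variance-stabilised scale decompose additively as
#' \eqn{y = m + a_t + b_q + \pi}. For every feature and each of the four
#' (target design, query design) reagent combinations, the target x query
#' matrix is decomposed by two-way median polish, which is robust to the
#' minority of interacting pairs; the residuals are the pi-scores. Per-design
#' effects are the average of a reagent's row (or column) effects over the
#' two polishes it participates in, re-centred so that the median over genes
#' of every (design, feature) effect slice is exactly zero (the median shift
#' is absorbed into the intercept).
#'
#' @param tensor a transformed \linkS4class{ScreenTensor}, at least
#'   10 x 10 genes.
#' @param eps median-polish convergence tolerance (on the change in the
#'   residual absolute sum).
#' @param maxIter maximum number of polish iterations.
#' @return a \linkS4class{MainEffects} object (effects plus the pi-score
#'   tensor). Genes with more than 50\% missing values in some polish matrix
#'   are reported in the flagged slots.
#' @examples
#' sim <- simulateScreen(simulationConfig(nTargets = 12, nQueries = 10,
#'                                        nFeatures = 4, seed = 1L))
#' vst <- VstParams(lambda = setNames(rep(1, 4), featureNames(sim$tensor)))
#' fit <- fitMainEffects(applyVst(sim$tensor, vst))
#' fit
#' @export
fitMainEffects <- function(tensor, eps = 1e-9, maxIter = 100L) {
  stopifnot(is(tensor, "ScreenTensor"))
  if (!tensor@transformed)
    warning("tensor does not appear to be variance-stabilised")
  v <- tensor@values
  d <- dim(v)
  if (d[1L] < 10L || d[3L] < 10L)
    stop("median polish requires at least a 10 x 10 gene matrix")
  dn <- dimnames(v)
  tg <- dn[[1L]]; qg <- dn[[3L]]; feats <- dn[[5L]]
  pi <- array(NA_real_, dim = d, dimnames = dn)
  aSum <- array(0, c(d[1L], 2L, d[5L]), dimnames = list(tg, dn[[2L]], feats))
  bSum <- array(0, c(d[3L], 2L, d[5L]), dimnames = list(qg, dn[[4L]], feats))
  mPair <- array(NA_real_, c(2L, 2L, d[5L]),
                 dimnames = list(dn[[2L]], dn[[4L]], feats))
  flagT <- character(); flagQ <- character()
  for (f in seq_len(d[5L])) {
    for (i in 1:2) for (j in 1:2) {
      m <- v[, i, , j, f]
      rowMiss <- rowMeans(is.na(m)); colMiss <- colMeans(is.na(m))
      flagT <- union(flagT, tg[rowMiss > 0.5])
      flagQ <- union(flagQ, qg[colMiss > 0.5])
      mp <- .polishMatrix(m, eps = eps, maxIter = maxIter)
      pi[, i, , j, f] <- mp$residuals
      mPair[i, j, f] <- mp$overall
      aSum[, i, f] <- aSum[, i, f] + mp$row / 2
      bSum[, j, f] <- bSum[, j, f] + mp$col / 2
    }
    ## exact median centring: shift gene-effect medians into the intercept
    for (i in 1:2) {
      med <- stats::median(aSum[, i, f], na.rm = TRUE)
      aSum[, i, f] <- aSum[, i, f] - med
      mPair[i, , f] <- mPair[i, , f] + med
    }
    for (j in 1:2) {
      med <- stats::median(bSum[, j, f], na.rm = TRUE)
      bSum[, j, f] <- bSum[, j, f] - med
      mPair[, j, f] <- mPair[, j, f] + med
    }
  }
  MainEffects(intercept = stats::setNames(apply(mPair, 3L, mean), feats),
              interceptByPair = mPair, target = aSum, query = bSum, pi = pi,
              flaggedTargets = flagT, flaggedQueries = flagQ)
}

#' Empirical-Bayes moderated one-sample t-test
#'
#' Shrinks per-group sample variances towards a pooled prior variance
#' \eqn{s_0^2} with prior degrees of freedom \eqn{d_0} estimated across all
#' groups by moment matching on log sample variances (scaled F-distribution
#' fit), then tests each group mean against zero with
#' \eqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)} and
#' \eqn{t = \bar{x}/(\tilde{s}/\sqrt{n})} on \eqn{d_0 + d} degrees of
#' freedom. In the limit \eqn{d_0 \to \infty} the statistic reduces to the
#' closed form \eqn{\bar{x}/(s_0/\sqrt{n})}.
#'
#' @param means group sample means.
#' @param vars group sample variances (NA where n < 2).
#' @param ns group sizes.
#' @param d0,s0sq optional fixed hyperparameters; estimated from \code{vars}
#'   when \code{NULL}. \code{d0 = Inf} selects the pure-prior limit.
#' @return list with elements \code{t}, \code{p} (two-sided), \code{df},
#'   \code{d0}, \code{s0sq}. Groups with \code{ns < 2} get NA statistics.
#' @export
moderatedTTest <- function(means, vars, ns, d0 = NULL, s0sq = NULL) {
  stopifnot(length(means) == length(vars), length(vars) == length(ns))
  ok <- ns >= 2L & !is.na(vars)
  if (is.null(d0) || is.null(s0sq)) {
    if (!any(ok)) stop("no group with at least 2 observations")
    if (all(vars[ok] == 0)) {
      warning("all sample variances are zero; using the d0 = Inf branch")
      d0 <- Inf; s0sq <- 0
    } else {
      fd <- tryCatch(limma::fitFDist(vars[ok], df1 = ns[ok] - 1L),
                     error = function(e) NULL)
      if (is.null(fd) || !is.finite(fd$scale)) {
        warning("prior fit failed; falling back to d0 = Inf with pooled s0")
        d0 <- Inf; s0sq <- mean(vars[ok])
      } else {
        d0 <- fd$df2; s0sq <- fd$scale
      }
    }
  }
  df <- ns - 1
  s2post <- if (is.infinite(d0)) rep(s0sq, length(vars))
            else (d0 * s0sq + df * vars) / (d0 + df)
  tstat <- means / sqrt(s2post / ns)
  tstat[s2post == 0] <- ifelse(means[s2post == 0] == 0, 0,
                               sign(means[s2post == 0]) * Inf)
  dfTotal <- d0 + df
  p <- 2 * stats::pt(-abs(tstat), dfTotal)
  p[!is.na(tstat) & tstat == 0] <- 1
  tstat[!ok] <- NA_real_; p[!ok] <- NA_real_
  list(t = tstat, p = p, df = dfTotal, d0 = d0, s0sq = s0sq)
}

#' Summarise gene-pair interactions with a moderated t-test
#'
#' For each gene pair and feature, the up to four reagent-pair pi-scores are
#' tested against the null hypothesis that their mean is zero using the
#' empirical-Bayes moderated t-test (hyperparameters estimated per feature by
#' pooling all gene pairs), and p-values are adjusted per feature across all
#' gene pairs by Benjamini-Hochberg. Pairs with fewer than two reagent-pair
#' values are not tested.
#'
#' @param x a \linkS4class{MainEffects} object or a 5-D pi-score array.
#' @return an \linkS4class{InteractionStats} object.
#' @export
summarizeInteractions <- function(x) {
  pi <- if (is(x, "MainEffects")) x@pi else x
  stopifnot(is.array(pi), length(dim(pi)) == 5L)
  d <- dim(pi); dn <- dimnames(pi)
  tg <- dn[[1L]]; qg <- dn[[3L]]; feats <- dn[[5L]]
  nPairs <- d[1L] * d[3L]
  tabs <- vector("list", d[5L])
  d0s <- s0s <- stats::setNames(numeric(d[5L]), feats)
  for (f in seq_len(d[5L])) {
    m4 <- matrix(aperm(pi[, , , , f, drop = FALSE], c(1L, 3L, 2L, 4L, 5L)),
                 nrow = nPairs, ncol = 4L)
    n <- rowSums(!is.na(m4))
    mean4 <- rowMeans(m4, na.rm = TRUE)
    mean4[n == 0L] <- NA_real_
    ss <- rowSums(m4^2, na.rm = TRUE)
    s2 <- (ss - n * mean4^2) / (n - 1)
    s2[n < 2L] <- NA_real_
    s2 <- pmax(s2, 0)  # guard tiny negative from cancellation
    mt <- moderatedTTest(mean4, s2, n)
    padj <- rep(NA_real_, nPairs)
    tested <- !is.na(mt$p)
    padj[tested] <- stats::p.adjust(mt$p[tested], method = "BH")
    tabs[[f]] <- data.frame(
      target = rep(tg, times = d[3L]), query = rep(qg, each = d[1L]),
      feature = feats[f], mean_pi = mean4, n = n,
      t = mt$t, p = mt$p, p_adj = padj)
    d0s[f] <- mt$d0; s0s[f] <- mt$s0sq
  }
  InteractionStats(table = do.call(rbind, tabs), priorDf = d0s,
                   priorVar = s0s)
}

#' Test single-gene phenotypes against a null reference
#'
#' Moderated t-test of each target gene's per-design main-effect estimates
#' against the null centre, per feature, with Benjamini-Hochberg adjustment
#' within feature. A gene is called significant when its adjusted p-value is
#' strictly below \code{fdr} in at least one feature.
#'
#' @param effects a \linkS4class{MainEffects} object.
#' @param nullReference per-feature null values: either a named numeric
#'   vector of null centres, or a matrix of control measurements (features in
#'   columns) whose column means are used. Required.
#' @param fdr FDR threshold for the significance call (default 0.01).
#' @return list with \code{table} (gene, feature, effect, t, p, p_adj) and
#'   \code{significantGenes}.
#' @export
testSingleGenePhenotypes <- function(effects, nullReference, fdr = 0.01) {
  stopifnot(is(effects, "MainEffects"))
  if (missing(nullReference) || is.null(nullReference))
    stop("a null reference (control values or null centres) is required")
  feats <- names(effects@intercept)
  centre <- if (is.matrix(nullReference)) colMeans(nullReference, na.rm = TRUE)
            else nullReference
  if (is.null(names(centre)) || !all(feats %in% names(centre)))
    stop("null reference must cover every feature by name")
  a <- effects@target
  genes <- dimnames(a)[[1L]]
  tabs <- vector("list", length(feats))
  for (f in seq_along(feats)) {
    est <- a[, , f]                     # genes x 2 designs
    n <- rowSums(!is.na(est))
    m <- rowMeans(est, na.rm = TRUE) - centre[[feats[f]]]
    v <- apply(est, 1L, stats::var)
    mt <- moderatedTTest(m, v, n)
    padj <- rep(NA_real_, length(genes))
    tested <- !is.na(mt$p)
    padj[tested] <- stats::p.adjust(mt$p[tested], method = "BH")
    tabs[[f]] <- data.frame(gene = genes, feature = feats[f], effect = m,
                            t = mt$t, p = mt$p, p_adj = padj)
  }
  tab <- do.call(rbind, tabs)
  sig <- unique(tab$gene[!is.na(tab$p_adj) & tab$p_adj < fdr])
  list(table = tab, significantGenes = sig)
}

#' Per-feature and cumulative interaction counts
#'
#' Counts significant interactions per feature, split by the sign of the mean
#' pi-score, and the cumulative number of gene pairs with a significant
#' interaction in at least one of the first k features of a given ordering.
#'
#' @param stats an \linkS4class{InteractionStats} object.
#' @param fdr FDR threshold (strict inequality, default 0.01).
#' @param featureOrder ordering for the cumulative curve; defaults to the
#'   feature order in the table.
#' @return list with \code{perFeature} (feature, positive, negative, total)
#'   and \code{cumulative} (k, feature, pairs, fraction of all pairs).
#' @export
interactionRateSummary <- function(stats, fdr = 0.01, featureOrder = NULL) {
  tb <- stats@table
  feats <- unique(tb$feature)
  if (is.null(featureOrder)) featureOrder <- feats
  stopifnot(all(featureOrder %in% feats))
  sig <- !is.na(tb$p_adj) & tb$p_adj < fdr
  perFeature <- do.call(rbind, lapply(feats, function(f) {
    s <- sig & tb$feature == f
    data.frame(feature = f,
               positive = sum(s & tb$mean_pi > 0),
               negative = sum(s & tb$mean_pi < 0),
               total = sum(s))
  }))
  pairId <- paste(tb$target, tb$query, sep = "\r")
  allPairs <- unique(pairId)
  seen <- logical(length(allPairs))
  names(seen) <- allPairs
  cum <- integer(length(featureOrder))
  for (k in seq_along(featureOrder)) {
    s <- sig & tb$feature == featureOrder[k]
    seen[unique(pairId[s])] <- TRUE
    cum[k] <- sum(seen)
  }
  list(perFeature = perFeature,
       cumulative = data.frame(k = seq_along(featureOrder),
                               feature = featureOrder, pairs = cum,
                               fraction = cum / length(allPairs)))
}

#' Export interaction statistics as TSV
#'
#' @param stats an \linkS4class{InteractionStats}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeInteractionStats <- function(stats, path) {
  stopifnot(is(stats, "InteractionStats"))
  utils::write.table(stats@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
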