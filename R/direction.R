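#' @include AllClasses.R AllGenerics.R
NULL

#' Fit the direction model for one gene pair
#'
#' Fits the pair's multivariate interaction vector as a linear combination of
#' the two single-gene effect vectors, \eqn{\pi = \alpha a + \beta b}
#' (no intercept: pi and the effect vectors are centred/residual
#' quantities), and quantifies by analysis of variance how much of the
#' pi-score sum of squares is explained by each gene. Fractions use the
#' order-invariant extra sum of squares of each covariate given the other
#' (type II), divided by the total sum of squares of pi and clamped to
#' [0, 1]; with orthogonal effect vectors the two fractions and the residual
#' fraction add to 1 exactly.
#'
#' @param piVec interaction vector over features; a matrix (rows = stacked
#'   reagent-pair observations) is also accepted, in which case \code{aVec}
#'   and \code{bVec} must be matrices of matching covariate rows.
#' @param aVec,bVec single-gene effect vectors of gene A and gene B over the
#'   same features.
#' @param collinearityLimit pairs whose effect vectors have
#'   |cos angle| above this limit are flagged unidentifiable (direction is
#'   meaningless for near-identical phenotypes).
#' @return one-row data.frame: \code{alpha}, \code{beta}, \code{frac_a},
#'   \code{frac_b}, \code{resid_frac}, \code{n_obs},
#'   \code{unidentifiable}.
#' @examples
#' directionFit(c(0, -1), aVec = c(1, 0), bVec = c(0, 1))
#' @export
directionFit <- function(piVec, aVec, bVec, collinearityLimit = 0.99) {
  y <- as.vector(t(piVec))
  A <- as.vector(t(aVec)); B <- as.vector(t(bVec))
  stopifnot(length(A) == length(y), length(B) == length(y))
  ok <- is.finite(y) & is.finite(A) & is.finite(B)
  y <- y[ok]; A <- A[ok]; B <- B[ok]
  out <- data.frame(alpha = NA_real_, beta = NA_real_, frac_a = NA_real_,
                    frac_b = NA_real_, resid_frac = NA_real_,
                    n_obs = length(y), unidentifiable = TRUE)
  if (length(y) < 2L) return(out)
  na <- sqrt(sum(A^2)); nb <- sqrt(sum(B^2))
  if (na == 0 || nb == 0 || abs(sum(A * B)) / (na * nb) > collinearityLimit)
    return(out)
  tot <- sum(y^2)
  if (tot == 0) {
    out[1L, ] <- list(0, 0, 0, 0, 0, length(y), FALSE)
    return(out)
  }
  qrFull <- qr(cbind(a = A, b = B))
  cf <- qr.coef(qrFull, y)
  rssFull <- sum(qr.resid(qrFull, y)^2)
  rssA <- sum(qr.resid(qr(cbind(A)), y)^2)   # model with a only
  rssB <- sum(qr.resid(qr(cbind(B)), y)^2)   # model with b only
  clamp <- function(z) max(0, min(1, z))
  out[1L, ] <- list(unname(cf["a"]), unname(cf["b"]),
                    clamp((rssB - rssFull) / tot),
                    clamp((rssA - rssFull) / tot),
                    clamp(rssFull / tot), length(y), FALSE)
  out
}

#' Fit the direction model for all gene pairs of a screen
#'
#' For every (target, query) gene pair, fits the pair's pi-score vector over
#' all features against the two genes' main-effect vectors and records the
#' explained sum-of-squares fractions. By default the up to four reagent-pair
#' pi vectors are averaged into one gene-level vector per pair (and effect
#' vectors are averaged over the two designs); \code{aggregate = "stack"}
#' instead stacks the reagent-pair observations with design-matched effect
#' vectors as covariates.
#'
#' Fits are computed for all pairs — the threshold quantiles are taken over
#' the whole screen — while directional calls are later restricted to pairs
#' with a significant interaction.
#'
#' @param effects a \linkS4class{MainEffects} object.
#' @param stats optional \linkS4class{InteractionStats}; when supplied, a
#'   \code{significant} column marks pairs with BH-adjusted p below
#'   \code{fdr} in at least one feature.
#' @param fdr FDR threshold for the significance flag (default 0.01, strict).
#' @param aggregate \code{"average"} (default) or \code{"stack"}.
#' @param collinearityLimit see [directionFit()].
#' @return data.frame with one row per gene pair: \code{target},
#'   \code{query}, the [directionFit()] columns with \code{frac_target} /
#'   \code{frac_query} naming the two sides, and \code{significant}.
#' @export
fitDirectionModels <- function(effects, stats = NULL, fdr = 0.01,
                               aggregate = c("average", "stack"),
                               collinearityLimit = 0.99) {
  stopifnot(is(effects, "MainEffects"))
  aggregate <- match.arg(aggregate)
  pi <- effects@pi
  d <- dim(pi); dn <- dimnames(pi)
  if (d[5L] < 2L) stop("direction fitting needs at least 2 features")
  tg <- dn[[1L]]; qg <- dn[[3L]]
  aBar <- apply(effects@target, c(1L, 3L), mean, na.rm = TRUE)
  bBar <- apply(effects@query, c(1L, 3L), mean, na.rm = TRUE)
  sigPairs <- NULL
  if (!is.null(stats)) {
    tb <- stats@table
    s <- !is.na(tb$p_adj) & tb$p_adj < fdr
    sigPairs <- unique(paste(tb$target[s], tb$query[s], sep = "\r"))
  }
  rows <- vector("list", d[1L] * d[3L])
  k <- 0L
  for (qi in seq_len(d[3L])) for (ti in seq_len(d[1L])) {
    k <- k + 1L
    if (aggregate == "average") {
      pv <- apply(pi[ti, , qi, , ], 3L, mean, na.rm = TRUE)
      fit <- directionFit(pv, aBar[ti, ], bBar[qi, ], collinearityLimit)
    } else {
      pv <- rbind(pi[ti, 1L, qi, 1L, ], pi[ti, 1L, qi, 2L, ],
                  pi[ti, 2L, qi, 1L, ], pi[ti, 2L, qi, 2L, ])
      av <- effects@target[ti, c(1L, 1L, 2L, 2L), ]
      bv <- effects@query[qi, c(1L, 2L, 1L, 2L), ]
      fit <- directionFit(pv, av, bv, collinearityLimit)
    }
    rows[[k]] <- cbind(data.frame(target = tg[ti], query = qg[qi]), fit)
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "frac_a"] <- "frac_target"
  names(out)[names(out) == "frac_b"] <- "frac_query"
  if (!is.null(sigPairs))
    out$significant <- paste(out$target, out$query, sep = "\r") %in% sigPairs
  out
}

#' Derive direction-call thresholds from the screen-wide fraction quantiles
#'
#' The lower and upper thresholds are the empirical \code{qLow} and
#' \code{qHigh} quantiles (linear interpolation) of the pooled
#' explained-sum-of-squares fractions of both genes over all fitted gene
#' pairs.
#'
#' @param fits data.frame from [fitDirectionModels()].
#' @param qLow,qHigh quantile levels; defaults 0.10 and 0.95.
#' @return named numeric \code{c(low = , high = )}.
#' @export
deriveThresholds <- function(fits, qLow = 0.10, qHigh = 0.95) {
  stopifnot(qLow < qHigh)
  pool <- c(fits$frac_target[!fits$unidentifiable],
            fits$frac_query[!fits$unidentifiable])
  pool <- pool[!is.na(pool)]
  if (length(pool) < 40L)
    stop("need at least 20 fitted pairs to derive stable quantile thresholds")
  thr <- stats::quantile(pool, c(qLow, qHigh), names = FALSE, type = 7L)
  if (thr[1L] >= thr[2L])
    stop("degenerate fraction distribution: thresholds coincide")
  c(low = thr[1L], high = thr[2L])
}

#' Call signed, directed epistatic interactions
#'
#' Emits a directed call from gene A to gene B when the fraction of pi-score
#' sum of squares explained by A is below the lower threshold while the
#' fraction explained by B is above the upper threshold (and symmetrically
#' for B to A); since the lower threshold is below the upper one, at most
#' one call per pair is possible. The sign comes from the fitted coefficient
#' on the downstream (called) gene's effect vector: alleviating when
#' negative (the double knockdown dampens that gene's phenotype),
#' aggravating when positive. Only pairs flagged significant are eligible;
#' unidentifiable fits are skipped.
#'
#' @param fits data.frame from [fitDirectionModels()].
#' @param thresholds named numeric from [deriveThresholds()].
#' @return data.frame with columns \code{source}, \code{target},
#'   \code{sign}, \code{coefficient}, \code{frac_source},
#'   \code{frac_target_gene}.
#' @export
callDirections <- function(fits, thresholds) {
  stopifnot(all(c("low", "high") %in% names(thresholds)),
            thresholds["low"] < thresholds["high"])
  eligible <- if ("significant" %in% names(fits)) fits$significant else TRUE
  f <- fits[eligible & !fits$unidentifiable & !is.na(fits$frac_target), ]
  lo <- thresholds[["low"]]; hi <- thresholds[["high"]]
  tq <- f$frac_target < lo & f$frac_query > hi   # target gene -> query gene
  qt <- f$frac_query < lo & f$frac_target > hi   # query gene -> target gene
  out <- rbind(
    data.frame(source = f$target[tq], target = f$query[tq],
               coefficient = f$beta[tq],
               frac_source = f$frac_target[tq],
               frac_target_gene = f$frac_query[tq]),
    data.frame(source = f$query[qt], target = f$target[qt],
               coefficient = f$alpha[qt],
               frac_source = f$frac_query[qt],
               frac_target_gene = f$frac_target[qt]))
  out$sign <- ifelse(out$coefficient < 0, "alleviating", "aggravating")
  out[, c("source", "target", "sign", "coefficient", "frac_source",
          "frac_target_gene")]
}

#' Export directed calls as TSV or GraphML
#'
#' @param calls data.frame from [callDirections()].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeDirectionCalls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeDirectionCalls
#' @export
writeDirectionGraphML <- function(calls, path) {
  g <- igraph::graph_from_data_frame(
    calls[, c("source", "target", "sign", "coefficient")], directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
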