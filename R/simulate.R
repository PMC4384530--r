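#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a simulation configuration
#'
#' Validated constructor for \linkS4class{SimulationConfig}; see that class
#' for the meaning and defaults of every study condition.
#'
#' @param nTargets,nQueries,nFeatures screen dimensions.
#' @param featureNames feature labels (first three default to the seed
#'   phenotypes).
#' @param effectSd main-effect SD on the transformed scale.
#' @param interactingFraction fraction of gene pairs with an interaction.
#' @param directionalFraction fraction of interacting pairs that are
#'   directional.
#' @param directionCoef coefficient magnitude |c| of directional pairs.
#' @param alleviatingFraction fraction of directional pairs with c < 0.
#' @param symmetricPiSd per-feature SD of symmetric interaction scores.
#' @param noiseSd measurement noise SD.
#' @param discordantFraction fraction of targets with an off-target second
#'   design.
#' @param discordantShiftSd SD of the reagent deviations of discordant
#'   designs.
#' @param nComplexes,complexSize,complexPiSd planted profile-sharing groups.
#' @param lambda VST cofactor(s) for emitting raw-scale values.
#' @param seed integer random seed.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nTargets = 50L, nQueries = 12L, nFeatures = 20L,
                             featureNames = NULL, effectSd = 1,
                             interactingFraction = 0.10,
                             directionalFraction = 0.5,
                             directionCoef = 0.8,
                             alleviatingFraction = 0.5,
                             symmetricPiSd = 0.8, noiseSd = 0.25,
                             discordantFraction = 0.06,
                             discordantShiftSd = 3,
                             nComplexes = 0L, complexSize = 5L,
                             complexPiSd = 0.8,
                             lambda = 1, seed = 1L) {
  if (is.null(featureNames)) {
    seedNames <- c("cell_number", "mitotic_index", "cell_area")
    featureNames <- c(seedNames[seq_len(min(3L, nFeatures))],
                      if (nFeatures > 3L)
                        sprintf("feature_%02d", seq_len(nFeatures - 3L)))
  }
  new("SimulationConfig",
      nTargets = as.integer(nTargets), nQueries = as.integer(nQueries),
      nFeatures = as.integer(nFeatures), featureNames = featureNames,
      effectSd = effectSd, interactingFraction = interactingFraction,
      directionalFraction = directionalFraction,
      directionCoef = directionCoef,
      alleviatingFraction = alleviatingFraction,
      symmetricPiSd = symmetricPiSd, noiseSd = noiseSd,
      discordantFraction = discordantFraction,
      discordantShiftSd = discordantShiftSd,
      nComplexes = as.integer(nComplexes),
      complexSize = as.integer(complexSize), complexPiSd = complexPiSd,
      lambda = lambda, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nTargets, "targets x", object@nQueries,
      "queries x 2 x 2 designs x", object@nFeatures, "features\n")
  cat(sprintf("  interacting %.0f%% (directional %.0f%%, |c| = %.2f), noise SD %.2f, discordant designs %.0f%%\n",
              100 * object@interactingFraction,
              100 * object@directionalFraction, object@directionCoef,
              object@noiseSd, 100 * object@discordantFraction))
  if (object@nComplexes > 0L)
    cat("  planted complexes:", object@nComplexes, "x", object@complexSize,
        "genes\n")
  cat("  seed:", object@seed, "\n")
})

#' Generate a synthetic combinatorial RNAi screen with known ground truth
#'
#' Emits a raw-scale double-knockdown tensor built, on the transformed
#' scale, as \eqn{y = m + a + b + \pi + \varepsilon} with i.i.d. Gaussian
#' noise. A random subset of gene pairs carries planted interactions:
#' directional pairs get \eqn{\pi = c \cdot} (downstream gene's effect
#' vector) exactly (before noise), with c negative for alleviating and
#' positive for aggravating relations; symmetric pairs get isotropic
#' Gaussian pi-scores; optional planted complexes are groups of targets
#' sharing one interaction profile across all queries. Planted discordant
#' targets receive large additive deviations on a random half of the
#' features in their second dsRNA design, emulating off-target reagents.
#' Raw-scale values are produced by inverting the variance-stabilising
#' transformation; single-knockdown replicate tables are two independent
#' noise draws of \eqn{m + a}. Everything is reproducible from the seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{tensor} (raw-scale
#'   \linkS4class{ScreenTensor}), \code{singles} (list of two raw-scale
#'   experiments x features replicate matrices over the target
#'   knockdowns), \code{vst} (the \linkS4class{VstParams} used), and
#'   \code{truth}: a list with the transformed-scale \code{m}, \code{a},
#'   \code{b}, \code{pi} (gene-level targets x queries x features),
#'   \code{directed} (data.frame source, target, sign, coefficient, and the
#'   roles of the two genes), \code{symmetricPairs},
#'   \code{discordantTargets}, \code{complexes} (named membership vector)
#'   and \code{interactingPairs}.
#' @examples
#' sim <- simulateScreen(simulationConfig(nTargets = 12, nQueries = 10,
#'                                        nFeatures = 4, seed = 7L))
#' names(sim$truth)
#' @export
simulateScreen <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  Tn <- config@nTargets; Qn <- config@nQueries; Fn <- config@nFeatures
  feats <- config@featureNames
  tg <- sprintf("t%03d", seq_len(Tn))
  qg <- sprintf("q%03d", seq_len(Qn))
  designs <- c("ds1", "ds2")
  lambda <- stats::setNames(rep_len(config@lambda, Fn), feats)

  m <- stats::setNames(stats::rnorm(Fn, mean = 4, sd = 0.5), feats)
  aGene <- matrix(stats::rnorm(Tn * Fn, sd = config@effectSd), Tn,
                  dimnames = list(tg, feats))
  bGene <- matrix(stats::rnorm(Qn * Fn, sd = config@effectSd), Qn,
                  dimnames = list(qg, feats))

  ## per-design effects; discordant targets get an off-target second design
  a <- aperm(array(aGene, c(Tn, Fn, 2L),
                   dimnames = list(tg, feats, designs)), c(1L, 3L, 2L))
  b <- aperm(array(bGene, c(Qn, Fn, 2L),
                   dimnames = list(qg, feats, designs)), c(1L, 3L, 2L))
  nDisc <- round(config@discordantFraction * Tn)
  discordant <- sort(sample(tg, nDisc))
  for (g in discordant) {
    shifted <- sample(Fn, max(1L, round(Fn / 2)))
    a[g, 2L, shifted] <- a[g, 2L, shifted] +
      stats::rnorm(length(shifted), sd = config@discordantShiftSd)
  }

  ## planted complexes claim targets first; remaining pairs may interact
  complexes <- integer(0)
  piGene <- array(0, c(Tn, Qn, Fn), dimnames = list(tg, qg, feats))
  complexTargets <- character(0)
  if (config@nComplexes > 0L) {
    complexTargets <- sample(tg, config@nComplexes * config@complexSize)
    complexes <- stats::setNames(rep(seq_len(config@nComplexes),
                                     each = config@complexSize),
                                 complexTargets)
    for (cx in seq_len(config@nComplexes)) {
      profile <- matrix(stats::rnorm(Qn * Fn, sd = config@complexPiSd),
                        Qn, Fn)
      for (g in names(complexes)[complexes == cx])
        piGene[g, , ] <- profile
    }
  }

  freeIdx <- which(!(rep(tg, times = Qn) %in% complexTargets))
  nInt <- round(config@interactingFraction * Tn * Qn)
  intIdx <- sort(sample(freeIdx, min(nInt, length(freeIdx))))
  nDir <- round(config@directionalFraction * length(intIdx))
  dirIdx <- if (nDir > 0L) sort(sample(intIdx, nDir)) else integer(0)
  symIdx <- setdiff(intIdx, dirIdx)
  pairGenes <- function(idx) {
    t <- (idx - 1L) %% Tn + 1L
    q <- (idx - 1L) %/% Tn + 1L
    list(t = tg[t], q = qg[q])
  }
  directed <- data.frame(source = character(), target = character(),
                         sign = character(), coefficient = numeric(),
                         target_gene_role = character(),
                         query_gene_role = character())
  for (idx in dirIdx) {
    pg <- pairGenes(idx)
    cc <- config@directionCoef *
      (if (stats::runif(1) < config@alleviatingFraction) -1 else 1)
    towardsQuery <- stats::runif(1) < 0.5
    if (towardsQuery) {   # target gene modifies the query gene's phenotype
      piGene[pg$t, pg$q, ] <- cc * bGene[pg$q, ]
      directed <- rbind(directed, data.frame(
        source = pg$t, target = pg$q,
        sign = if (cc < 0) "alleviating" else "aggravating",
        coefficient = cc, target_gene_role = "source",
        query_gene_role = "downstream"))
    } else {
      piGene[pg$t, pg$q, ] <- cc * aGene[pg$t, ]
      directed <- rbind(directed, data.frame(
        source = pg$q, target = pg$t,
        sign = if (cc < 0) "alleviating" else "aggravating",
        coefficient = cc, target_gene_role = "downstream",
        query_gene_role = "source"))
    }
  }
  symmetricPairs <- data.frame(target = character(), query = character())
  for (idx in symIdx) {
    pg <- pairGenes(idx)
    piGene[pg$t, pg$q, ] <- stats::rnorm(Fn, sd = config@symmetricPiSd)
    symmetricPairs <- rbind(symmetricPairs,
                            data.frame(target = pg$t, query = pg$q))
  }

  ## assemble transformed-scale tensor: y = m + a + b + pi + noise
  y <- array(NA_real_, c(Tn, 2L, Qn, 2L, Fn),
             dimnames = list(tg, designs, qg, designs, feats))
  for (f in seq_len(Fn))
    for (i in 1:2) for (j in 1:2)
      y[, i, , j, f] <- m[[f]] + outer(a[, i, f], b[, j, f], "+") +
        piGene[, , f]
  if (config@noiseSd > 0)
    y <- y + array(stats::rnorm(length(y), sd = config@noiseSd), dim(y))
  vst <- VstParams(lambda = lambda)
  rawTensor <- inverseVst(ScreenTensor(values = y, transformed = TRUE), vst)

  singles <- lapply(1:2, function(r) {
    mat <- sweep(aGene, 2L, m, "+") +
      matrix(stats::rnorm(Tn * Fn, sd = config@noiseSd), Tn)
    dimnames(mat) <- list(tg, feats)
    inverseVst(mat, vst)
  })

  interacting <- rbind(
    if (length(dirIdx)) {
      pg <- pairGenes(dirIdx); data.frame(target = pg$t, query = pg$q,
                                          kind = "directional")
    },
    if (length(symIdx)) {
      pg <- pairGenes(symIdx); data.frame(target = pg$t, query = pg$q,
                                          kind = "symmetric")
    },
    if (length(complexTargets)) {
      data.frame(target = rep(complexTargets, each = Qn),
                 query = rep(qg, times = length(complexTargets)),
                 kind = "complex")
    })

  list(tensor = rawTensor, singles = singles, vst = vst,
       truth = list(m = m, a = a, b = b, pi = piGene, directed = directed,
                    symmetricPairs = symmetricPairs,
                    discordantTargets = discordant,
                    complexes = complexes,
                    interactingPairs = interacting))
}

#' Generate replicate feature tables with planted latent factors
#'
#' Builds two replicate experiments x features tables for studying the
#' step-wise feature selection: the three seed phenotypes each carry their
#' own latent factor; \code{nFactors} additional features carry independent
#' reproducible factors (shared between replicates, so their residual
#' correlation is high); \code{nRedundant} features are noisy copies of the
#' seeds (no new reproducible information); and \code{nNoise} features are
#' pure independent noise in each replicate.
#'
#' @param nExperiments number of experiments (rows).
#' @param nFactors number of informative non-seed features.
#' @param nRedundant number of noisy seed copies.
#' @param nNoise number of pure-noise features.
#' @param noiseSd replicate noise SD; with unit-variance factors the
#'   replicate correlation of an informative feature is
#'   \eqn{1/(1 + \sigma^2)} (default 0.5, giving 0.8).
#' @param seed random seed.
#' @return list with matrices \code{rep1}, \code{rep2}, and
#'   \code{informative}: the names of the planted factor-bearing non-seed
#'   features.
#' @export
simulateReplicateFeatures <- function(nExperiments = 1000L, nFactors = 5L,
                                      nRedundant = 6L, nNoise = 6L,
                                      noiseSd = 0.5, seed = 1L) {
  set.seed(seed)
  seeds <- c("cell_number", "mitotic_index", "cell_area")
  factorNames <- if (nFactors > 0L) sprintf("factor_%02d", seq_len(nFactors))
                 else character(0)
  redundantNames <- if (nRedundant > 0L)
    sprintf("redundant_%02d", seq_len(nRedundant)) else character(0)
  noiseNames <- if (nNoise > 0L) sprintf("noise_%02d", seq_len(nNoise))
                else character(0)
  feats <- c(seeds, factorNames, redundantNames, noiseNames)
  Z <- matrix(stats::rnorm(nExperiments * (3L + nFactors)), nExperiments)
  draw <- function() {
    mat <- matrix(stats::rnorm(nExperiments * length(feats), sd = noiseSd),
                  nExperiments, length(feats), dimnames = list(NULL, feats))
    mat[, seeds] <- mat[, seeds] + Z[, 1:3]
    if (nFactors > 0L)
      mat[, factorNames] <- mat[, factorNames] +
        Z[, 3L + seq_len(nFactors), drop = FALSE]
    if (nRedundant > 0L)
      mat[, redundantNames] <- mat[, redundantNames] +
        Z[, rep_len(1:3, nRedundant), drop = FALSE]
    mat
  }
  list(rep1 = draw(), rep2 = draw(), informative = factorNames)
}

#' Score pipeline recovery against simulation ground truth
#'
#' Compares the calls of a full analysis run with the planted structure of
#' the synthetic screen it was run on: sensitivity and precision of
#' symmetric interaction detection at the given FDR, the fraction of planted
#' directed pairs that received a directional call, direction and
#' direction-plus-sign accuracy among those calls, and the fraction of
#' planted symmetric (non-directional) pairs that wrongly received a
#' directional call.
#'
#' @param truth the \code{truth} element of [simulateScreen()] output.
#' @param calls data.frame from [callDirections()].
#' @param stats an \linkS4class{InteractionStats} from the same screen.
#' @param fdr FDR threshold used for interaction detection (default 0.01).
#' @return list of metrics; \code{precision} is NA when nothing was
#'   detected.
#' @export
evaluateRecovery <- function(truth, calls, stats, fdr = 0.01) {
  tb <- stats@table
  universe <- unique(c(tb$target, tb$query))
  truthGenes <- c(rownames(truth$pi), colnames(truth$pi))
  if (!all(universe %in% truthGenes))
    stop("gene universes of truth and stats do not match")
  ## planted pairs involving genes removed upstream (e.g. by QC) cannot be
  ## recovered and are excluded from the denominators
  inU <- function(df) df[df[[1L]] %in% universe & df[[2L]] %in% universe, ,
                         drop = FALSE]
  interacting <- inU(truth$interactingPairs)
  directedTruth <- inU(truth$directed)
  symmetric <- inU(truth$symmetricPairs)

  sig <- !is.na(tb$p_adj) & tb$p_adj < fdr
  detected <- unique(paste(tb$target[sig], tb$query[sig], sep = "\r"))
  trueInt <- paste(interacting$target, interacting$query, sep = "\r")
  sensitivity <- if (length(trueInt)) mean(trueInt %in% detected) else NA_real_
  precision <- if (length(detected)) mean(detected %in% trueInt) else NA_real_

  callKey <- paste(calls$source, calls$target, sep = "\r")
  dirFwd <- paste(directedTruth$source, directedTruth$target, sep = "\r")
  dirRev <- paste(directedTruth$target, directedTruth$source, sep = "\r")
  gotCall <- dirFwd %in% callKey | dirRev %in% callKey
  directionRecall <- if (nrow(directedTruth)) mean(gotCall) else NA_real_
  correctDir <- dirFwd %in% callKey
  signOk <- logical(nrow(directedTruth))
  for (i in seq_len(nrow(directedTruth))) {
    if (!correctDir[i]) next
    got <- calls[callKey == dirFwd[i], , drop = FALSE][1L, ]
    signOk[i] <- got$sign == directedTruth$sign[i]
  }
  nCalled <- sum(gotCall)
  directionAccuracy <- if (nCalled) sum(correctDir & gotCall) / nCalled
                       else NA_real_
  directionSignAccuracy <- if (nCalled) sum(signOk) / nCalled else NA_real_

  symKeys <- c(paste(symmetric$target, symmetric$query, sep = "\r"),
               paste(symmetric$query, symmetric$target, sep = "\r"))
  nSym <- nrow(symmetric)
  falseDirectionRate <- if (nSym)
    sum(unique(callKey) %in% symKeys) / nSym else NA_real_

  list(sensitivity = sensitivity, precision = precision,
       directionRecall = directionRecall,
       directionAccuracy = directionAccuracy,
       directionSignAccuracy = directionSignAccuracy,
       falseDirectionRate = falseDirectionRate,
       nDetected = length(detected), nCalls = nrow(calls))
}
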