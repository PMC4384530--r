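test_that("simulation is bit-reproducible from its seed", {
  cfg <- simulationConfig(nTargets = 12, nQueries = 10, nFeatures = 4,
                          seed = 99L)
  s1 <- simulateScreen(cfg)
  s2 <- simulateScreen(cfg)
  expect_identical(tensorValues(s1$tensor), tensorValues(s2$tensor))
  expect_identical(s1$singles, s2$singles)
  expect_identical(s1$truth, s2$truth)
})

test_that("invalid configurations fail before any generation", {
  expect_error(simulationConfig(nTargets = 5), "at least 10")
  expect_error(simulationConfig(interactingFraction = 1.2), "\\[0, 1\\]")
  expect_error(simulationConfig(lambda = -1), "positive")
  expect_error(simulationConfig(nComplexes = 5L, complexSize = 11L,
                                nTargets = 50L), "complexes")
})

test_that("planted directed pairs satisfy the exact pre-noise relation", {
  sim <- simulateScreen(simulationConfig(noiseSd = 0, seed = 77L,
                                         discordantFraction = 0))
  tr <- sim$truth
  for (k in seq_len(nrow(tr$directed))) {
    d <- tr$directed[k, ]
    if (d$target_gene_role == "source") {       # target modifies query
      piVec <- tr$pi[d$source, d$target, ]
      bVec <- apply(tr$b[d$target, , ], 2, mean)
      expect_equal(piVec, d$coefficient * bVec, tolerance = 1e-12)
    } else {                                    # query modifies target
      piVec <- tr$pi[d$target, d$source, ]
      aVec <- apply(tr$a[d$target, , ], 2, mean)
      expect_equal(piVec, d$coefficient * aVec, tolerance = 1e-12)
    }
  }
})

test_that("a noiseless non-interacting screen closes the loop exactly", {
  sim <- simulateScreen(simulationConfig(nTargets = 15, nQueries = 12,
                                         nFeatures = 4, noiseSd = 0,
                                         interactingFraction = 0,
                                         discordantFraction = 0,
                                         seed = 13L))
  tt <- applyVst(sim$tensor, sim$vst)
  # the raw tensor inverts back to the exact transformed-scale values
  fit <- fitMainEffects(tt)
  expect_lt(max(abs(piScores(fit))), 1e-8)
  for (i in 1:2) for (f in 1:4) {
    aTrue <- sim$truth$a[, i, f]
    expect_equal(unname(targetEffects(fit)[, i, f]),
                 unname(aTrue - median(aTrue)), tolerance = 1e-8)
  }
})

test_that("fitted direction coefficients track the planted values", {
  run <- benchmarkRun()
  tr <- run$sim$truth$directed
  fits <- run$fits
  key <- paste(fits$target, fits$query)
  coefHat <- coefTrue <- numeric(0)
  for (k in seq_len(nrow(tr))) {
    d <- tr[k, ]
    pairKey <- if (d$target_gene_role == "source")
      paste(d$source, d$target) else paste(d$target, d$source)
    row <- fits[match(pairKey, key), ]
    if (is.na(row$alpha)) next    # pair removed by QC upstream
    coefHat <- c(coefHat,
                 if (d$target_gene_role == "source") row$beta else row$alpha)
    coefTrue <- c(coefTrue, d$coefficient)
  }
  # the typical planted pair recovers its coefficient to within 0.1,
  # and estimates track the planted +/-0.8 coefficients closely
  expect_lt(median(abs(coefHat - coefTrue)), 0.1)
  expect_gt(cor(coefHat, coefTrue), 0.95)
})

test_that("recovery scoring behaves on perfect and empty call sets", {
  truth <- list(
    pi = matrix(0, 2, 2, dimnames = list(c("t1", "t2"), c("q1", "q2"))),
    directed = data.frame(source = "t1", target = "q1",
                          sign = "alleviating", coefficient = -0.8,
                          target_gene_role = "source",
                          query_gene_role = "downstream"),
    symmetricPairs = data.frame(target = "t2", query = "q2"),
    interactingPairs = data.frame(target = c("t1", "t2"),
                                  query = c("q1", "q2"),
                                  kind = c("directional", "symmetric")))
  tb <- expand.grid(target = c("t1", "t2"), query = c("q1", "q2"),
                    feature = "f", stringsAsFactors = FALSE)
  tb$mean_pi <- c(-1, 0, 0, 1); tb$n <- 4L; tb$t <- 0
  tb$p <- c(2.5e-4, 1, 1, 2.5e-4)
  tb$p_adj <- c(0.001, 1, 1, 0.001)
  stats <- InteractionStats(table = tb, priorDf = c(f = 10),
                            priorVar = c(f = 1))
  perfect <- data.frame(source = "t1", target = "q1", sign = "alleviating",
                        coefficient = -0.8, frac_source = 0.01,
                        frac_target_gene = 0.99)
  rec <- evaluateRecovery(truth, perfect, stats)
  expect_equal(rec$sensitivity, 1)
  expect_equal(rec$precision, 1)
  expect_equal(rec$directionRecall, 1)
  expect_equal(rec$directionAccuracy, 1)
  expect_equal(rec$directionSignAccuracy, 1)
  expect_equal(rec$falseDirectionRate, 0)
  empty <- perfect[0, ]
  rec0 <- evaluateRecovery(truth, empty, stats)
  expect_equal(rec0$directionRecall, 0)
  # unknown genes in the stats table are rejected
  badTb <- tb; badTb$target[1] <- "unknown_gene"
  badStats <- InteractionStats(table = badTb, priorDf = c(f = 10),
                               priorVar = c(f = 1))
  expect_error(evaluateRecovery(truth, perfect, badStats), "universe")
})

test_that("recovery degrades monotonically with noise", {
  sens <- sapply(c(0.1, 0.45, 1.2), function(noise) {
    mean(sapply(c(101L, 202L, 303L), function(seed) {
      sim <- simulateScreen(simulationConfig(
        nTargets = 20, nQueries = 10, nFeatures = 8, noiseSd = noise,
        discordantFraction = 0, seed = seed))
      tt <- applyVst(sim$tensor, sim$vst)
      eff <- fitMainEffects(tt)
      st <- summarizeInteractions(eff)
      fits <- fitDirectionModels(eff, st)
      calls <- callDirections(fits, deriveThresholds(fits))
      evaluateRecovery(sim$truth, calls, st)$sensitivity
    }))
  })
  expect_true(all(diff(sens) <= 0.02))  # non-increasing up to MC jitter
})

test_that("replicate feature tables carry the advertised factor structure", {
  sim <- simulateReplicateFeatures(nExperiments = 600, nFactors = 2,
                                   nRedundant = 2, nNoise = 2, seed = 7L)
  expect_identical(colnames(sim$rep1), colnames(sim$rep2))
  # informative features correlate ~0.8 between replicates, noise ~0
  for (f in sim$informative)
    expect_equal(cor(sim$rep1[, f], sim$rep2[, f]), 0.8, tolerance = 0.08)
  expect_lt(abs(cor(sim$rep1[, "noise_01"], sim$rep2[, "noise_01"])), 0.15)
})
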