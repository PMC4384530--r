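test_that("median polish exactly decomposes noiseless additive tensors", {
  fx <- makeAdditiveTensor(nT = 20, nQ = 20, nF = 2, seed = 30)
  fit <- fitMainEffects(fx$tensor)
  expect_lt(max(abs(piScores(fit))), 1e-9)
  # effects recovered up to the median-zero centring
  for (i in 1:2) for (f in 1:2) {
    aHat <- targetEffects(fit)[, i, f]
    aTrue <- fx$a[, i, f] - median(fx$a[, i, f])
    expect_equal(unname(aHat), unname(aTrue), tolerance = 1e-9)
    bHat <- queryEffects(fit)[, i, f]
    bTrue <- fx$b[, i, f] - median(fx$b[, i, f])
    expect_equal(unname(bHat), unname(bTrue), tolerance = 1e-9)
  }
  # effect medians are centred at zero by construction
  expect_lt(max(abs(apply(targetEffects(fit), c(2, 3), median))), 1e-8)
  expect_lt(max(abs(apply(queryEffects(fit), c(2, 3), median))), 1e-8)
})

test_that("a single planted cell is returned as its own pi-score", {
  fx <- makeAdditiveTensor(nT = 20, nQ = 20, nF = 1, seed = 31)
  v <- tensorValues(fx$tensor)
  delta <- 1.7
  v["t005", 1, "q011", 2, 1] <- v["t005", 1, "q011", 2, 1] + delta
  fit <- fitMainEffects(ScreenTensor(values = v, transformed = TRUE))
  pi <- piScores(fit)
  expect_equal(pi["t005", 1, "q011", 2, 1], delta, tolerance = 1e-6)
  pi["t005", 1, "q011", 2, 1] <- 0
  expect_lt(max(abs(pi)), 1e-6)
})

test_that("pi-score row and column medians vanish at convergence", {
  sim <- simulateScreen(simulationConfig(nTargets = 15, nQueries = 12,
                                         nFeatures = 4, seed = 32L))
  fit <- fitMainEffects(applyVst(sim$tensor, sim$vst))
  pi <- piScores(fit)
  for (f in 1:4) for (i in 1:2) for (j in 1:2) {
    m <- pi[, i, , j, f]
    expect_lt(max(abs(apply(m, 1, median))), 1e-8)
    expect_lt(max(abs(apply(m, 2, median))), 1e-8)
  }
})

test_that("main-effect estimates are robust to sparse contamination", {
  fx <- makeAdditiveTensor(nT = 20, nQ = 20, nF = 1, seed = 33)
  clean <- fitMainEffects(fx$tensor)
  v <- tensorValues(fx$tensor)
  set.seed(34)
  # contaminate 10% of the cells of one design-pair matrix
  idx <- cbind(sample(20, 40, TRUE), 1L, sample(20, 40, TRUE), 1L, 1L)
  idx <- idx[!duplicated(idx[, c(1, 3)]), , drop = FALSE]
  v[idx] <- v[idx] + rnorm(nrow(idx), 0, 5)
  dirty <- fitMainEffects(ScreenTensor(values = v, transformed = TRUE))
  expect_equal(targetEffects(dirty)[, 2, ], targetEffects(clean)[, 2, ],
               tolerance = 1e-6)
  expect_equal(queryEffects(dirty)[, 2, ], queryEffects(clean)[, 2, ],
               tolerance = 1e-6)
})

test_that("small or unusable matrices are rejected or flagged", {
  fx <- makeAdditiveTensor(nT = 5, nQ = 20, nF = 1, seed = 35)
  expect_error(fitMainEffects(fx$tensor), "10 x 10")
  fx2 <- makeAdditiveTensor(nT = 12, nQ = 12, nF = 1, seed = 36)
  v <- tensorValues(fx2$tensor)
  v["t003", 1, seq(1, 12, by = 2), 1, 1] <- NA  # >50% missing in one row
  v["t003", 1, c(2, 4, 6, 8), 1, 1] <- NA
  fit <- fitMainEffects(ScreenTensor(values = v, transformed = TRUE))
  expect_true("t003" %in% fit@flaggedTargets)
})

test_that("the moderated t-test matches its closed-form prior limit", {
  means <- c(0.5, -1, 0, 2)
  vars <- c(0.2, 0.5, 0.1, 0.4)
  ns <- rep(4L, 4)
  mt <- moderatedTTest(means, vars, ns, d0 = Inf, s0sq = 0.3)
  expect_equal(mt$t, means / (sqrt(0.3) / 2), tolerance = 1e-8)
  # zero means with zero variance: t = 0, p = 1
  mt0 <- moderatedTTest(0, 0, 4L, d0 = Inf, s0sq = 0)
  expect_equal(mt0$t, 0)
  expect_equal(mt0$p, 1)
})

test_that("interaction summaries agree with an independent moderated-test route", {
  # dual route: summarizeInteractions vs the linear-model empirical-Bayes
  # pipeline of limma applied to the same per-pair quadruplets
  set.seed(37)
  nT <- 10; nQ <- 10
  pi <- array(rnorm(nT * 2 * nQ * 2, sd = 0.5),
              c(nT, 2, nQ, 2, 1),
              dimnames = list(sprintf("t%02d", 1:nT), c("d1", "d2"),
                              sprintf("q%02d", 1:nQ), c("d1", "d2"), "f"))
  pi[1, , 1, , 1] <- pi[1, , 1, , 1] + 2
  st <- summarizeInteractions(pi)
  tb <- interactionTable(st)
  quad <- t(apply(expand.grid(t = 1:nT, q = 1:nQ), 1,
                  function(ix) as.vector(pi[ix[1], , ix[2], , 1])))
  fitL <- limma::eBayes(limma::lmFit(quad, design = matrix(1, 4, 1)))
  # both tables enumerate pairs with the target index varying fastest
  expect_equal(tb$t, as.vector(fitL$t), tolerance = 1e-8)
  expect_equal(tb$p, as.vector(fitL$p.value), tolerance = 1e-8)
  expect_equal(unname(priorDf(st)["f"]), fitL$df.prior, tolerance = 1e-6)
  expect_equal(unname(priorVar(st)["f"]), fitL$s2.prior, tolerance = 1e-6)
})

test_that("null pi-scores produce calibrated adjusted p-values", {
  set.seed(38)
  pi <- array(rnorm(50 * 2 * 40 * 2), c(50, 2, 40, 2, 1),
              dimnames = list(sprintf("t%02d", 1:50), c("d1", "d2"),
                              sprintf("q%02d", 1:40), c("d1", "d2"), "f"))
  tb <- interactionTable(summarizeInteractions(pi))
  expect_lte(mean(tb$p_adj < 0.01, na.rm = TRUE), 0.012)
  # BH properties: adjusted >= raw, monotone in raw p
  ord <- order(tb$p)
  expect_true(all(tb$p_adj[ord] >= tb$p[ord] - 1e-12))
  expect_true(all(diff(tb$p_adj[ord]) >= -1e-12))
})

test_that("all-zero pi quadruplets give t = 0 and p = 1", {
  pi <- array(rnorm(12 * 2 * 12 * 2, sd = 0.3), c(12, 2, 12, 2, 1),
              dimnames = list(sprintf("t%02d", 1:12), c("d1", "d2"),
                              sprintf("q%02d", 1:12), c("d1", "d2"), "f"))
  pi[3, , 4, , 1] <- 0
  # the planted zero-variance quadruplet makes the prior fit warn
  tb <- interactionTable(suppressWarnings(summarizeInteractions(pi)))
  row <- tb[tb$target == "t03" & tb$query == "q04", ]
  expect_equal(row$mean_pi, 0)
  expect_equal(row$t, 0)
  expect_equal(row$p, 1)
})

test_that("pairs with fewer than two values are not tested", {
  pi <- array(rnorm(10 * 2 * 10 * 2), c(10, 2, 10, 2, 1),
              dimnames = list(sprintf("t%02d", 1:10), c("d1", "d2"),
                              sprintf("q%02d", 1:10), c("d1", "d2"), "f"))
  pi[1, , 2, , 1] <- c(0.5, NA, NA, NA)
  tb <- interactionTable(summarizeInteractions(pi))
  row <- tb[tb$target == "t01" & tb$query == "q02", ]
  expect_equal(row$n, 1L)
  expect_true(is.na(row$t) && is.na(row$p) && is.na(row$p_adj))
})

test_that("single-gene phenotype testing detects planted effects only", {
  fx <- makeAdditiveTensor(nT = 30, nQ = 12, nF = 2, seed = 39)
  v <- tensorValues(fx$tensor) + rnorm(length(tensorValues(fx$tensor)),
                                       sd = 0.2)
  fit <- fitMainEffects(ScreenTensor(values = v, transformed = TRUE))
  centres <- setNames(rep(0, 2), names(effectIntercept(fit)))
  expect_error(testSingleGenePhenotypes(fit, NULL), "null reference")
  # calibration on a null screen without planted effects
  v0 <- array(4, dim(v), dimnames = dimnames(v)) +
    rnorm(length(v), sd = 0.2)
  fit0 <- fitMainEffects(ScreenTensor(values = v0, transformed = TRUE))
  res0 <- testSingleGenePhenotypes(fit0, centres)
  expect_lte(length(res0$significantGenes) / 30, 0.1)
  # a 10-null-SD planted effect is recovered
  v1 <- v0
  v1["t007", , , , 1] <- v1["t007", , , , 1] + 10 * 0.2
  fit1 <- fitMainEffects(ScreenTensor(values = v1, transformed = TRUE))
  res1 <- testSingleGenePhenotypes(fit1, centres)
  expect_true("t007" %in% res1$significantGenes)
})

test_that("interaction-rate summaries accumulate pairs across features", {
  set.seed(40)
  pi <- array(rnorm(12 * 2 * 12 * 2 * 8, sd = 0.2), c(12, 2, 12, 2, 8),
              dimnames = list(sprintf("t%02d", 1:12), c("d1", "d2"),
                              sprintf("q%02d", 1:12), c("d1", "d2"),
                              sprintf("f%d", 1:8)))
  pi[2, , 3, , c(3, 7)] <- 4   # one pair interacting in features 3 and 7
  st <- suppressWarnings(summarizeInteractions(pi))  # planted zero variances
  rate <- interactionRateSummary(st)
  expect_equal(rate$perFeature$positive[3], 1)
  expect_equal(rate$perFeature$positive[7], 1)
  expect_true(all(diff(rate$cumulative$pairs) >= 0))
  expect_equal(rate$cumulative$pairs[2], 0)
  expect_equal(rate$cumulative$pairs[3], 1)  # enters the curve at k = 3
  expect_equal(rate$cumulative$pairs[8], 1)
  # empty case: no significant pairs, flat zero curve
  rate0 <- interactionRateSummary(summarizeInteractions(
    array(rnorm(12 * 2 * 12 * 2, sd = 0.2), c(12, 2, 12, 2, 1),
          dimnames = dimnames(pi)[c(1:4)] |> c(list("f1")))))
  expect_true(all(rate0$perFeature$total == 0))
  expect_true(all(rate0$cumulative$pairs == 0))
})
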