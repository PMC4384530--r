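test_that("direction fits reproduce exact algebra on orthonormal effect vectors", {
  a <- c(1, 0); b <- c(0, 1)
  f1 <- directionFit(c(0, -1), a, b)
  expect_equal(f1$alpha, 0)
  expect_equal(f1$beta, -1)
  expect_equal(f1$frac_a, 0)
  expect_equal(f1$frac_b, 1)
  f2 <- directionFit(c(1, 0), a, b)
  expect_equal(f2$alpha, 1)
  expect_equal(f2$frac_a, 1)
  expect_equal(f2$frac_b, 0)
  # hand least squares on orthonormal covariates: pi = (0.5, 0.5)
  f3 <- directionFit(c(0.5, 0.5), a, b)
  expect_equal(f3$frac_a, 0.5)
  expect_equal(f3$frac_b, 0.5)
})

test_that("fractions and residual add to one for orthogonal effect vectors", {
  set.seed(50)
  for (rep in 1:20) {
    a <- rnorm(10)
    b0 <- rnorm(10)
    b <- b0 - sum(b0 * a) / sum(a * a) * a   # orthogonalise
    pi <- rnorm(10)
    f <- directionFit(pi, a, b)
    expect_lt(abs(f$frac_a + f$frac_b + f$resid_frac - 1), 1e-10)
    expect_true(f$frac_a >= 0 && f$frac_a <= 1)
    expect_true(f$frac_b >= 0 && f$frac_b <= 1)
  }
})

test_that("swapping gene labels swaps sides but preserves the relation", {
  set.seed(51)
  a <- rnorm(15); b <- rnorm(15)
  pi <- -0.7 * b + rnorm(15, sd = 0.1)
  fwd <- directionFit(pi, a, b)
  rev <- directionFit(pi, b, a)
  expect_equal(fwd$frac_a, rev$frac_b, tolerance = 1e-12)
  expect_equal(fwd$frac_b, rev$frac_a, tolerance = 1e-12)
  expect_equal(fwd$alpha, rev$beta, tolerance = 1e-12)
  expect_equal(fwd$beta, rev$alpha, tolerance = 1e-12)
})

test_that("joint positive scaling leaves fractions and calls unchanged", {
  set.seed(52)
  a <- rnorm(12); b <- rnorm(12)
  pi <- 0.9 * b + rnorm(12, sd = 0.05)
  f1 <- directionFit(pi, a, b)
  f2 <- directionFit(17.3 * pi, 17.3 * a, 17.3 * b)
  expect_equal(f1$frac_a, f2$frac_a, tolerance = 1e-9)
  expect_equal(f1$frac_b, f2$frac_b, tolerance = 1e-9)
})

test_that("collinear effect vectors are unidentifiable", {
  a <- c(1, 2, 3, 4)
  f <- directionFit(c(0.1, 0.2, 0.3, 0.4), a, 1.0001 * a)
  expect_true(f$unidentifiable)
  expect_true(is.na(f$alpha))
})

test_that("threshold quantiles track the pooled fraction distribution", {
  set.seed(53)
  fits <- makeFitsTable(runif(5000), runif(5000))
  thr <- deriveThresholds(fits)
  expect_equal(unname(thr["low"]), 0.10, tolerance = 0.01)
  expect_equal(unname(thr["high"]), 0.95, tolerance = 0.01)
  # permutation invariance
  thr2 <- deriveThresholds(fits[sample(nrow(fits)), ])
  expect_equal(thr, thr2)
  # degenerate distribution and too-few fits both error
  expect_error(deriveThresholds(makeFitsTable(rep(0.5, 100), rep(0.5, 100))),
               "degenerate")
  expect_error(deriveThresholds(makeFitsTable(runif(10), runif(10))),
               "at least 20")
  expect_error(deriveThresholds(fits, qLow = 0.9, qHigh = 0.1))
})

test_that("directional calls follow the two-threshold rule with signs from coefficients", {
  thr <- c(low = 0.1, high = 0.95)
  fits <- makeFitsTable(fracT = c(0.02, 0.98, 0.5, 0.02),
                        fracQ = c(0.98, 0.02, 0.5, 0.98),
                        beta = c(-0.9, 0.4, -0.5, 0.7),
                        alpha = c(0.1, 0.8, 0.2, 0.3))
  calls <- callDirections(fits, thr)
  expect_equal(nrow(calls), 3L)
  # pair 1: target gene explains nothing, query gene everything -> A001->B001
  c1 <- calls[calls$source == "A001", ]
  expect_equal(c1$target, "B001")
  expect_equal(c1$sign, "alleviating")      # beta < 0
  # pair 2: reversed sides -> B002->A002, sign from alpha > 0
  c2 <- calls[calls$source == "B002", ]
  expect_equal(c2$target, "A002")
  expect_equal(c2$sign, "aggravating")
  # pair 3 (0.5 / 0.5): no call
  expect_false(any(calls$source %in% c("A003", "B003")))
  # pair 4 with positive beta: aggravating
  expect_equal(calls$sign[calls$source == "A004"], "aggravating")
})

test_that("non-significant and unidentifiable pairs are never called", {
  thr <- c(low = 0.1, high = 0.95)
  fits <- makeFitsTable(fracT = c(0.02, 0.02), fracQ = c(0.98, 0.98),
                        beta = -1, significant = c(FALSE, TRUE))
  expect_equal(nrow(callDirections(fits, thr)), 1L)
  fits$unidentifiable[2] <- TRUE
  expect_equal(nrow(callDirections(fits, thr)), 0L)
})

test_that("an interaction antiparallel to one gene's phenotype is called alleviating towards it", {
  # a pair whose interaction vector opposes the downstream gene's effects:
  # the upstream anaphase-promoting-complex-like gene is called alleviating
  set.seed(54)
  bSti <- rnorm(21)                       # downstream gene effect vector
  aCdc <- rnorm(21)
  pi <- -0.9 * bSti + rnorm(21, sd = 0.05)
  fit <- directionFit(pi, aCdc, bSti)
  fits <- cbind(data.frame(target = "Cdc23", query = "sti"), fit)
  names(fits)[names(fits) == "frac_a"] <- "frac_target"
  names(fits)[names(fits) == "frac_b"] <- "frac_query"
  fits$significant <- TRUE
  calls <- callDirections(fits, c(low = 0.1, high = 0.95))
  expect_equal(calls$source, "Cdc23")
  expect_equal(calls$target, "sti")
  expect_equal(calls$sign, "alleviating")
})

test_that("planted directed relations are recovered accurately on the benchmark screen", {
  run <- benchmarkRun()
  rec <- run$recovery
  # every emitted call on a planted directed pair has the right direction
  # and sign, and planted symmetric pairs are almost never called
  expect_gte(rec$directionAccuracy, 0.95)
  expect_gte(rec$directionSignAccuracy, 0.95)
  expect_lte(rec$falseDirectionRate, 0.05)
  expect_gt(rec$directionRecall, 0)
  # the quantile thresholds respect their defining levels
  pool <- c(run$fits$frac_target, run$fits$frac_query)
  expect_equal(mean(pool < run$thresholds["low"], na.rm = TRUE), 0.10,
               tolerance = 0.02)
})

test_that("stacked and averaged aggregation agree on strong planted pairs", {
  run <- benchmarkRun()
  fitsStacked <- fitDirectionModels(run$effects, run$stats,
                                    aggregate = "stack")
  tr <- run$sim$truth$directed
  key <- paste(run$fits$target, run$fits$query)
  keyS <- paste(fitsStacked$target, fitsStacked$query)
  dirKey <- ifelse(tr$target_gene_role == "source",
                   paste(tr$source, tr$target),
                   paste(tr$target, tr$source))
  dirKey <- dirKey[dirKey %in% key]
  avgHi <- pmax(run$fits$frac_target, run$fits$frac_query)[match(dirKey, key)]
  stkHi <- pmax(fitsStacked$frac_target,
                fitsStacked$frac_query)[match(dirKey, keyS)]
  expect_gt(cor(avgHi, stkHi, use = "complete.obs"), 0.8)
})

test_that("directed calls serialise as TSV and GraphML", {
  calls <- data.frame(source = c("geneA", "geneB"),
                      target = c("geneC", "geneA"),
                      sign = c("alleviating", "aggravating"),
                      coefficient = c(-0.8, 0.5),
                      frac_source = c(0.01, 0.02),
                      frac_target_gene = c(0.97, 0.99))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeDirectionCalls(calls, tsv)
  expect_equal(read.delim(tsv)$sign, calls$sign)
  gml <- withr::local_tempfile(fileext = ".graphml")
  writeDirectionGraphML(calls, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_true(igraph::is_directed(g))
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::edge_attr(g, "sign"), calls$sign)
})
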