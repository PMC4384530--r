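# shared fixture builders (all data generated in code)

# noiseless additive tensor: y[t,i,q,j,f] = m_f + a[t,i,f] + b[q,j,f]
makeAdditiveTensor <- function(nT = 20, nQ = 20, nF = 2, seed = 1,
                               transformed = TRUE) {
  set.seed(seed)
  tg <- sprintf("t%03d", seq_len(nT))
  qg <- sprintf("q%03d", seq_len(nQ))
  feats <- sprintf("f%02d", seq_len(nF))
  m <- stats::setNames(rnorm(nF, 4, 0.5), feats)
  a <- array(rnorm(nT * 2 * nF), c(nT, 2, nF),
             dimnames = list(tg, c("ds1", "ds2"), feats))
  b <- array(rnorm(nQ * 2 * nF), c(nQ, 2, nF),
             dimnames = list(qg, c("ds1", "ds2"), feats))
  y <- array(NA_real_, c(nT, 2, nQ, 2, nF),
             dimnames = list(tg, c("ds1", "ds2"), qg, c("ds1", "ds2"),
                             feats))
  for (f in seq_len(nF))
    for (i in 1:2) for (j in 1:2)
      y[, i, , j, f] <- m[[f]] + outer(a[, i, f], b[, j, f], "+")
  list(tensor = ScreenTensor(values = y, transformed = transformed),
       m = m, a = a, b = b)
}

# fits table for threshold / calling tests
makeFitsTable <- function(fracT, fracQ, alpha = 0, beta = 0,
                          significant = TRUE) {
  n <- length(fracT)
  data.frame(target = sprintf("A%03d", seq_len(n)),
             query = sprintf("B%03d", seq_len(n)),
             alpha = rep_len(alpha, n), beta = rep_len(beta, n),
             frac_target = fracT, frac_query = fracQ,
             resid_frac = pmax(0, 1 - fracT - fracQ),
             n_obs = 20L, unidentifiable = FALSE,
             significant = rep_len(significant, n))
}

# standard benchmark run shared by direction / acceptance tests
benchmarkRun <- local({
  cache <- NULL
  function(seed = 3L) {
    if (!is.null(cache) && cache$seed == seed) return(cache)
    sim <- simulateScreen(simulationConfig(seed = seed))
    vst <- estimateVstParams(sim$tensor)
    tt <- applyVst(sim$tensor, vst)
    qc <- reagentConcordance(tt)
    eff <- fitMainEffects(filterScreen(tt, qc))
    st <- summarizeInteractions(eff)
    fits <- fitDirectionModels(eff, st)
    thr <- deriveThresholds(fits)
    calls <- callDirections(fits, thr)
    rec <- evaluateRecovery(sim$truth, calls, st)
    cache <<- list(seed = seed, sim = sim, tensor = tt, qc = qc,
                   effects = eff, stats = st, fits = fits,
                   thresholds = thr, calls = calls, recovery = rec)
    cache
  }
})
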