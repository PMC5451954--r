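test_that("initialization starts at the data-informed intercept, equal weights", {
  f <- addExpectedCounts(toyFrame(2, 2, 1, counts = array(4, c(2, 2, 1))))
  f@expected[] <- 4                              # y = e everywhere
  spec <- modelSpec("Alt1", 1)
  st <- initializeState(spec, f)
  expect_equal(st$alpha0, 0)
  p <- mixtureWeightsTwo(st$mixZ[, 1, 1], st$mixA[, 1, 1])
  expect_equal(unname(p[1, ]), c(0.5, 0.5))

  ## initialization is inside the prior support across the spec space
  g <- makeLattice(2, 2)
  for (variant in c("F2PRED", "Alt1", "Alt2", "Alt3a", "Alt3b"))
    for (K in 1:3) {
      if (variant %in% c("Alt3a", "Alt3b") && K < 2) next
      spec <- modelSpec(variant, K)
      fr <- addExpectedCounts(toyFrame(4, 3, K,
        counts = array(rpois(12 * K, 10), c(4, 3, K))))
      st <- initializeState(spec, fr)
      expect_true(is.finite(logPrior(spec, st, g)), info = paste(variant, K))
    }
})

test_that("the sampler is bit-reproducible under (seed, config)", {
  spec <- modelSpec("Alt1", 1)
  ds <- syntheticDataset(spec, 3, 3, 4, seed = 2)
  f <- recomputeExpected(ds$frame)
  cfg <- mcmcConfig(nChains = 2, nBurnin = 60, nSamples = 40, seed = 5)
  fit1 <- runMcmc(f, ds$graph, ds$cov, spec, cfg)
  fit2 <- runMcmc(f, ds$graph, ds$cov, spec, cfg)
  expect_identical(drawMatrix(fit1), drawMatrix(fit2))
  expect_identical(yRep(fit1), yRep(fit2))
  ## a different seed gives a different draw sequence
  fit3 <- runMcmc(f, ds$graph, ds$cov, spec,
                  mcmcConfig(nChains = 2, nBurnin = 60, nSamples = 40,
                             seed = 6))
  expect_false(identical(drawMatrix(fit1), drawMatrix(fit3)))
})

test_that("run preconditions are enforced", {
  spec <- modelSpec("Alt1", 1)
  ds <- syntheticDataset(spec, 2, 2, 3, seed = 4,
                         signal = signalSettings(betaS = 0.3))
  cfg <- mcmcConfig(nChains = 1, nBurnin = 10, nSamples = 10)
  ## coded cells must be imputed first
  coded <- addExpectedCounts(ds$codedFrame)
  if (any(codedMask(coded)))
    expect_error(runMcmc(coded, ds$graph, ds$cov, spec, cfg), "impute")
  ## expected counts required
  expect_error(runMcmc(ds$codedFrame, ds$graph, ds$cov, spec, cfg),
               "expected counts|impute")
  ## unstandardized covariates refused
  raw <- destandardizeCovariates(ds$cov)
  expect_error(runMcmc(recomputeExpected(ds$frame), ds$graph, raw, spec, cfg),
               "standardized")
  ## all-zero disease refused
  z <- ds$frame; z@counts[] <- 0
  z <- addExpectedCounts(z, rates = 1e-4)
  expect_error(runMcmc(z, ds$graph, ds$cov, spec, cfg), "all-zero")
})

test_that("Gelman-Rubin matches hand arithmetic and flags separation", {
  ## hand-computed oracle on a 2-chain x 4-draw array
  x1 <- c(1, 2, 3, 4); x2 <- c(2, 3, 4, 7)
  n <- 4
  W <- (var(x1) + var(x2)) / 2
  B <- n * var(c(mean(x1), mean(x2)))
  want <- sqrt(((n - 1) / n * W + B / n) / W)
  s <- fakeSamples(cbind(`alpha0[1]` = c(x1, x2)), rep(1:2, each = 4))
  got <- gelmanRubin(s)$rhat
  expect_equal(unname(got), want, tolerance = 1e-12)

  ## two identical chains: the implemented no-between-variance limit
  s2 <- fakeSamples(cbind(`alpha0[1]` = c(x1, x1)), rep(1:2, each = 4))
  expect_equal(unname(gelmanRubin(s2)$rhat), sqrt((n - 1) / n),
               tolerance = 1e-12)

  ## chains offset by a large constant scream non-convergence
  s3 <- fakeSamples(cbind(`alpha0[1]` = c(x1, x1 + 100)), rep(1:2, each = 4))
  expect_gt(unname(gelmanRubin(s3)$rhat), 10)
  expect_false(gelmanRubin(s3)$converged)

  expect_error(gelmanRubin(fakeSamples(cbind(`alpha0[1]` = x1), rep(1, 4))),
               "2 chains")
})

test_that("shared effects are stored once and drive every disease", {
  spec <- modelSpec("F2PRED", 2)
  ds <- syntheticDataset(spec, 2, 2, 3, seed = 9)
  f <- recomputeExpected(ds$frame)
  cfg <- mcmcConfig(nChains = 1, nBurnin = 80, nSamples = 40, seed = 3)
  fit <- runMcmc(f, ds$graph, ds$cov, spec, cfg)
  cn <- colnames(drawMatrix(fit))
  ## exactly one v field (no disease subscript) and one shared gamma
  expect_length(grep("^v\\[", cn), 4)
  expect_length(grep("^gamma\\[\\d+\\]$", cn), 3)
  expect_length(grep("^gamma\\[\\d+,\\d+\\]$", cn), 0)
  ## perturbing v_1 moves the predictor of both diseases
  st <- initializeState(spec, f, cov = ds$cov)
  st2 <- st; st2$v[1] <- st2$v[1] + 1
  d <- logRelativeRisk(spec, st2, ds$cov) - logRelativeRisk(spec, st, ds$cov)
  expect_true(all(abs(d[1, , 1]) > 0) && all(abs(d[1, , 2]) > 0))

  ## Alt1 (multi-disease) carries a disease-specific gamma instead
  specA <- modelSpec("Alt1", 2)
  fitA <- runMcmc(f, ds$graph, ds$cov, specA, cfg)
  cnA <- colnames(drawMatrix(fitA))
  expect_length(grep("^gamma\\[\\d+,\\d+\\]$", cnA), 6)
})

test_that("posterior means are invariant to the block update order", {
  ## tight-prior univariate Alt2 on a 2x2 lattice, 3 years
  spec <- modelSpec("Alt2", 1, C = 2)
  ds <- syntheticDataset(spec, 2, 2, 3, seed = 21,
                         signal = signalSettings(sdV = 0.3, sdGamma = 0.2))
  f <- recomputeExpected(ds$frame)
  cfgFixed <- mcmcConfig(nChains = 1, nBurnin = 800, nSamples = 1200,
                         seed = 31)
  cfgRandom <- mcmcConfig(nChains = 1, nBurnin = 800, nSamples = 1200,
                          seed = 32, randomizeOrder = TRUE)
  fit1 <- runMcmc(f, ds$graph, ds$cov, spec, cfgFixed)
  fit2 <- runMcmc(f, ds$graph, ds$cov, spec, cfgRandom)
  for (fam in c("gamma", "v")) {
    d1 <- paramDraws(fit1, fam); d2 <- paramDraws(fit2, fam)
    for (p in seq_len(ncol(d1))) {
      se <- sqrt(batchMcse(d1[, p])^2 + batchMcse(d2[, p])^2)
      expect_lt(abs(mean(d1[, p]) - mean(d2[, p])), 3 * se + 1e-8)
    }
  }
})
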