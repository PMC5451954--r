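test_that("rook lattices have the right geometry", {
  g <- makeLattice(2, 2)
  expect_equal(nNeighbors(g), rep(2L, 4))
  g <- makeLattice(3, 3)
  expect_equal(nNeighbors(g)[5], 4L)             # center node
  expect_equal(sort(unique(nNeighbors(g))), c(2L, 3L, 4L))
  ## edge count: rows*(cols-1) + cols*(rows-1)
  for (rc in list(c(2, 5), c(4, 4), c(3, 7))) {
    g <- makeLattice(rc[1], rc[2])
    expect_equal(sum(nNeighbors(g)) / 2, rc[1] * (rc[2] - 1) + rc[2] * (rc[1] - 1))
  }
  expect_error(makeLattice(1, 1), "isolated")
})

test_that("true states honor the requested signal settings", {
  g <- makeLattice(5, 5)
  spec <- modelSpec("Alt1", 1)
  ## all SDs zero -> all random effects zero
  st0 <- sampleTrueState(spec, g, 6, signal = signalSettings(
    sdU = 0, sdV = 0, sdGamma = 0, sdPhi = 0, sdZ = 0, sdMixA = 0))
  expect_true(all(st0$u == 0) && all(st0$v == 0) && all(st0$gamma == 0) &&
              all(st0$phi == 0) && all(st0$mixZ == 0) && all(st0$mixA == 0))

  ## CAR and walk fields are centered
  st <- sampleTrueState(spec, g, 6, seed = 2)
  expect_equal(mean(st$v), 0, tolerance = 1e-12)
  expect_equal(mean(st$gamma), 0, tolerance = 1e-12)

  ## iid effect SDs match the request within Monte Carlo error:
  ## 20x20 lattice, J = 10 gives 4000 phi values per draw
  g2 <- makeLattice(20, 20)
  st2 <- sampleTrueState(modelSpec("Alt1", 1), g2, 10, seed = 3,
                         signal = signalSettings(sdPhi = 0.3, sdU = 0.2))
  phis <- c(sapply(1:3, function(s)
    sampleTrueState(modelSpec("Alt1", 1), g2, 10, seed = 3 + s,
                    signal = signalSettings(sdPhi = 0.3))$phi))
  ## 12,000 iid values: requested sigma recovered within 2%
  expect_equal(sd(phis), 0.3, tolerance = 0.02)
  expect_equal(sd(st2$u), 0.2, tolerance = 0.05)
})

test_that("generated counts have the stated Poisson mean structure", {
  ## null state: mean of y/e over many cells is 1
  spec <- modelSpec("Alt1", 1, interceptOnly = TRUE)
  g <- makeLattice(2, 1)
  cov <- covariateSet(I = 2, J = 400)
  st <- sampleTrueState(spec, g, 400, signal = signalSettings(
    sdU = 0, sdV = 0, sdGamma = 0, sdPhi = 0, sdZ = 0, sdMixA = 0))
  st$alpha0 <- 0
  f <- generateCounts(spec, st, rep(5e4, 2), cov, 1e-4, seed = 5)
  e <- expectedCounts(f)
  expect_equal(mean(counts(f) / e), 1,
               tolerance = 3 * sqrt(1 / mean(e) / length(e)))

  ## e = 5, theta = 2: empirical mean of many draws is 10
  st$alpha0 <- log(2)
  ys <- unlist(lapply(1:40, function(s)
    counts(generateCounts(spec, st, rep(5e4, 2), cov, 1e-4, seed = 100 + s))))
  expect_equal(mean(ys), 10, tolerance = 3 * sqrt(10 / length(ys)))

  ## determinism and overflow guard
  f1 <- generateCounts(spec, st, rep(5e4, 2), cov, 1e-4, seed = 8)
  f2 <- generateCounts(spec, st, rep(5e4, 2), cov, 1e-4, seed = 8)
  expect_identical(counts(f1), counts(f2))
  stBig <- st; stBig$alpha0 <- 50
  expect_error(generateCounts(spec, stBig, rep(5e4, 2), cov, 1e-4, seed = 1),
               "overflow")
})

test_that("thresholding codes exactly the scheme's intervals", {
  ct <- array(c(0, 1, 3, 4, 5, 9), c(2, 3, 1))
  f <- toyFrame(2, 3, 1, counts = ct)
  fc <- applyThresholding(f)
  expect_equal(as.vector(counts(fc)), c(0, 5, 5, 5, 10, 10))
  expect_equal(as.vector(codedMask(fc)), c(FALSE, rep(TRUE, 5)))
  ct2 <- array(c(0, 10, 12, 47, 100, 9), c(2, 3, 1))
  fc2 <- applyThresholding(toyFrame(2, 3, 1, counts = ct2))
  expect_equal(as.vector(counts(fc2)), c(0, 10, 12, 47, 100, 10))  # exact 10 passes through uncoded
  expect_equal(as.vector(codedMask(fc2)), c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("threshold-impute round trip stays inside the true count's interval", {
  spec <- modelSpec("Alt1", 1)
  scheme <- defaultThresholdScheme()
  devs <- c()
  for (seed in 1:5) {
    ds <- syntheticDataset(spec, 4, 4, 6, seed = seed)
    truth <- counts(ds$frame)
    coded <- codedMask(ds$codedFrame)
    fi <- imputeThresholded(addExpectedCounts(ds$codedFrame), scheme,
                            seed = 50 + seed)
    imp <- counts(fi)
    for (r in seq_along(scheme@codes)) {
      inInterval <- truth >= scheme@lower[r] & truth <= scheme@upper[r]
      expect_true(all(imp[inInterval] >= scheme@lower[r] &
                      imp[inInterval] <= scheme@upper[r]))
    }
    expect_identical(imp[!coded], truth[!coded])
    devs <- c(devs, imp[coded] - truth[coded])
  }
  ## with matched expected counts the imputation is centered near truth
  expect_lt(abs(mean(devs)), 0.5)
})

test_that("SIR concentrates around theta as expected counts grow", {
  spec <- modelSpec("Alt1", 1)
  ds <- syntheticDataset(spec, 4, 4, 5, seed = 31,
                         popRange = c(5e7, 5e7))   # e ~ 5000 per cell
  f <- ds$frame
  theta <- exp(logRelativeRisk(spec, ds$state, ds$cov))
  relErr <- abs(computeSIR(f) / theta - 1)
  expect_lt(mean(relErr), 0.05)
})

test_that("the recovery harness reports a reproducible per-replicate table", {
  spec <- modelSpec("Alt1", 1)
  cfg <- mcmcConfig(nChains = 1, nBurnin = 80, nSamples = 60)
  r1 <- recoveryHarness(spec, signal = signalSettings(betaS = 0.4),
                        config = cfg, nReplicates = 2, seed = 5,
                        rows = 3, cols = 3, J = 4)
  expect_equal(nrow(r1), 2)
  expect_true(all(c("betaSCovered", "gammaCorr", "shareSpatialPreferred")
                  %in% names(r1)))
  r2 <- recoveryHarness(spec, signal = signalSettings(betaS = 0.4),
                        config = cfg, nReplicates = 2, seed = 5,
                        rows = 3, cols = 3, J = 4)
  expect_identical(r1, r2)
})
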