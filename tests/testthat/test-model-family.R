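test_that("two-component mixture weights are a logistic split", {
  expect_equal(unname(mixtureWeightsTwo(0, 0)[1, ]), c(0.5, 0.5))
  expect_equal(unname(mixtureWeightsTwo(30, 10)[1, ]), c(1, 0))
  ## independent evaluation of the logistic at 1.2
  expect_equal(unname(mixtureWeightsTwo(0.7, 0.5)[1, "S"]),
               exp(1.2) / (1 + exp(1.2)), tolerance = 1e-14)
})

test_that("three-component mixture weights normalize correctly", {
  expect_equal(unname(mixtureWeightsThree(rep(0, 3), rep(0, 3))[1, ]),
               rep(1 / 3, 3))
  p <- mixtureWeightsThree(c(20, -20, -20), rep(0, 3))
  expect_equal(unname(p[1, ]), c(1, 0, 0), tolerance = 1e-6)
  ## the interpretable example: weights (0.1, 0.5, 0.4) are attainable
  p <- mixtureWeightsThree(qlogis(c(0.1, 0.5, 0.4)), rep(0, 3))
  expect_equal(unname(p[1, ]), c(0.1, 0.5, 0.4), tolerance = 1e-12)
  expect_equal(sum(p), 1)
})

test_that("Alt3 temporal scalings behave at their anchors", {
  expect_equal(alt3Scale("Alt3a", c(-1, 0, 2.5), 0), c(0, 0, 0))
  expect_equal(alt3Scale("Alt3a", 1.5, 2), 3.0)
  g <- c(-1.3, 0, 0.4, 2)
  expect_equal(alt3Scale("Alt3b", g, 1), g)      # identity at rho = 1
  expect_equal(alt3Scale("Alt3b", -2, 3), -8)    # sign-preserving power
  expect_equal(alt3Scale("Alt3b", 0, 0.7), 0)
  expect_error(alt3Scale("Alt3b", 1, -1), "rho > 0")
  expect_error(alt3Scale("Alt1", 1, 1), "Alt3a/Alt3b")
})

test_that("log relative risk matches a hand-coded evaluation, all variants", {
  set.seed(42)
  g <- makeLattice(3, 3); J <- 4
  for (variant in c("F2PRED", "Alt1", "Alt2", "Alt3a", "Alt3b")) {
    for (K in 1:3) {
      if (variant %in% c("Alt3a", "Alt3b") && K < 2) next
      spec <- modelSpec(variant, K)
      cov <- covariateSet(matrix(rnorm(18), 9, 2), matrix(rnorm(J), J, 1),
                          array(rnorm(9 * J), c(9, J, 1)))
      st <- sampleTrueState(spec, g, J, seed = sample.int(1e6, 1),
                            signal = signalSettings(
                              betaS = c(0.5, -0.2), betaT = 0.3,
                              betaST = 0.1, mixLogitMean = 0.3))
      expect_equal(logRelativeRisk(spec, st, cov),
                   naivePredictor(spec, st, cov, 9, J, K),
                   tolerance = 1e-12, info = paste(variant, K))
    }
  }
})

test_that("predictor degenerate cases: zero state and mixture collapse", {
  g <- makeLattice(2, 2)
  spec <- modelSpec("F2PRED", 1)
  st <- sampleTrueState(spec, g, 3, signal = signalSettings(
    sdU = 0, sdV = 0, sdGamma = 0, sdPhi = 0, sdZ = 0, sdMixA = 0,
    alpha0 = 0.7))
  cov <- covariateSet(I = 4, J = 3)
  expect_equal(logRelativeRisk(spec, st, cov),
               array(0.7, c(4, 3, 1)))

  ## p -> 1 removes every temporal term
  st$u[] <- rnorm(4, 0, 0.3); st$v <- rnorm(4, 0, 0.3)
  st$gamma[] <- rnorm(3); st$phi[] <- rnorm(12)
  st$mixA[] <- 50                                # p = 1
  lp <- logRelativeRisk(spec, st, cov)
  for (j in 1:3)
    expect_equal(lp[, j, 1], 0.7 + st$u[, 1] + st$v, tolerance = 1e-10)

  expect_error(logRelativeRisk(spec, st, cov, 5, 1, 1), "out of range")
})

test_that("Alt2 with a vanishing temporal weight reproduces Alt1", {
  g <- makeLattice(3, 2); I <- 6; J <- 4
  cov <- covariateSet(spatial = matrix(rnorm(I), I, 1),
                      spacetime = array(rnorm(I * J), c(I, J, 1)), J = J)
  spec1 <- modelSpec("Alt1", 1)
  st1 <- sampleTrueState(spec1, g, J, seed = 5,
                         signal = signalSettings(betaS = 0.4, betaST = 0.2))
  st1$gamma[] <- 0                                # merge temporal terms away
  pS <- 0.3
  st1$mixZ[] <- 0; st1$mixA[] <- qlogis(pS)
  spec2 <- modelSpec("Alt2", 1)
  st2 <- sampleTrueState(spec2, g, J, seed = 5,
                         signal = signalSettings(betaS = 0.4, betaST = 0.2))
  st2$alpha0 <- st1$alpha0; st2$u <- st1$u; st2$v <- st1$v
  st2$betaS <- st1$betaS; st2$betaST <- st1$betaST
  st2$phi <- st1$phi; st2$gamma[] <- 0
  st2$mixZ[] <- 0
  st2$mixA[, , 1] <- qlogis(pS)      # q_S = 0.3
  st2$mixA[, , 2] <- -40             # q_T -> 0
  st2$mixA[, , 3] <- qlogis(1 - pS)  # q_ST = 0.7
  expect_equal(logRelativeRisk(spec2, st2, cov),
               logRelativeRisk(spec1, st1, cov), tolerance = 1e-8)
})

test_that("Poisson log-likelihood is exact and additive", {
  f <- toyFrame(1, 1, 1, counts = array(0, c(1, 1, 1)))
  f@expected <- array(1, c(1, 1, 1))
  spec <- modelSpec("Alt1", 1, interceptOnly = TRUE)
  st <- initializeState(spec, f)
  st$alpha0 <- 0
  ll <- logLikelihood(f, spec, st, covariateSet(I = 1, J = 1))
  expect_equal(ll$total, -1)                     # log P(0 | mu = 1)

  f@counts <- array(3, c(1, 1, 1)); f@expected <- array(2, c(1, 1, 1))
  ll <- logLikelihood(f, spec, st, covariateSet(I = 1, J = 1))
  expect_equal(ll$total, dpois(3, 2, log = TRUE))

  ## total equals the sum of the pointwise matrix on a random fit state
  g <- makeLattice(3, 3)
  spec <- modelSpec("Alt2", 2)
  st <- sampleTrueState(spec, g, 4, seed = 8)
  cov <- covariateSet(I = 9, J = 4)
  fr <- generateCounts(spec, st, rep(5e4, 9), cov, c(1e-4, 3e-4), seed = 9)
  ll <- logLikelihood(fr, spec, st, cov)
  expect_equal(ll$total, sum(ll$pointwise), tolerance = 1e-10)
})

test_that("log-prior: ICAR translation invariance, support bounds, variant equivalence", {
  g <- makeLattice(2, 2)
  spec <- modelSpec("Alt1", 1)
  st <- sampleTrueState(spec, g, 4, seed = 3)
  lp0 <- logPrior(spec, st, g)
  ## adding a constant to v leaves the ICAR pairwise kernel unchanged
  st2 <- st; st2$v <- st$v + 3.7
  expect_equal(logPrior(spec, st2, g), lp0, tolerance = 1e-10)

  ## SD outside (0, C) kills the density
  stBad <- st; stBad$sigma$v <- 10.1
  expect_identical(logPrior(spec, stBad, g), -Inf)
  stBad <- st; stBad$sigma$phi[1] <- -0.1
  expect_identical(logPrior(spec, stBad, g), -Inf)

  ## univariate Alt1 and F2PRED are the same model: identical log
  ## posterior at identical states
  fr <- generateCounts(spec, st, rep(4e4, 4), covariateSet(I = 4, J = 4),
                       1e-4, seed = 2)
  specF <- modelSpec("F2PRED", 1)
  cov <- covariateSet(I = 4, J = 4)
  expect_equal(logPrior(spec, st, g), logPrior(specF, st, g))
  expect_equal(logLikelihood(fr, spec, st, cov)$total,
               logLikelihood(fr, specF, st, cov)$total)
})

test_that("ICAR joint kernel implies the stated full conditionals", {
  ## on a 3-node path and a 2x2 grid: as a function of x_i, the joint
  ## pairwise-difference kernel must equal the Gaussian kernel
  ## N(mean of neighbors, 1/(n_i tau)) up to a constant in x_i
  path3 <- adjacencyGraph(c("a", "b", "c"), list(2L, c(1L, 3L), 2L))
  for (graph in list(path3, makeLattice(2, 2))) {
    I <- length(countyIds(graph))
    set.seed(17)
    for (rep in 1:3) {
      x <- rnorm(I); tau <- runif(1, 0.5, 3)
      for (i in seq_len(I)) {
        ni <- nNeighbors(graph)[i]
        mi <- mean(x[neighbors(graph)[[i]]])
        for (t in seq(-2, 2, by = 0.5)) {
          xt <- x; xt[i] <- t
          dJoint <- icarJointKernel(xt, tau, graph) -
            icarJointKernel(x, tau, graph)
          dCond <- -ni * tau / 2 * ((t - mi)^2 - (x[i] - mi)^2)
          expect_equal(dJoint, dCond, tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("mixture weights are a simplex for random logits, all variants", {
  set.seed(6)
  p2 <- mixtureWeightsTwo(rnorm(500, 0, 5), rnorm(500, 0, 5))
  expect_true(all(p2 >= 0 & p2 <= 1))
  expect_equal(unname(rowSums(p2)), rep(1, 500), tolerance = 1e-12)
  p3 <- mixtureWeightsThree(matrix(rnorm(1500, 0, 5), 500, 3),
                            matrix(rnorm(1500, 0, 5), 500, 3))
  expect_true(all(p3 >= 0 & p3 <= 1))
  expect_equal(unname(rowSums(p3)), rep(1, 500), tolerance = 1e-12)
})

test_that("model specs enforce variant/arity constraints", {
  expect_error(modelSpec("Alt3a", 1), "bivariate")
  expect_error(modelSpec("Alt9", 1), "Alt9")
  expect_error(modelSpec("Alt1", 4), "1, 2 or 3")
  s <- modelSpec("Alt2", 3, C = c(default = 10, v = 5))
  expect_equal(stmixmap:::.getC(s, "v"), 5)
  expect_equal(stmixmap:::.getC(s, "u"), 10)
})
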