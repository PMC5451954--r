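## naive two-loop WAIC, the independent oracle
naiveWaic <- function(ll) {
  S <- nrow(ll); n <- ncol(ll)
  lppd <- 0; p <- 0
  for (cc in seq_len(n)) {
    m <- 0
    for (s in seq_len(S)) m <- m + exp(ll[s, cc])
    lppd <- lppd + log(m / S)
    p <- p + var(ll[, cc])
  }
  c(waic = -2 * (lppd - p), pWaic = p)
}

test_that("WAIC equals the naive two-loop evaluation", {
  set.seed(31)
  for (rep in 1:20) {
    ll <- matrix(rnorm(5 * 4, -3, 1), 5, 4)
    w <- waic(ll)
    nv <- naiveWaic(ll)
    expect_equal(w$waic, unname(nv["waic"]), tolerance = 1e-10)
    expect_equal(w$pWaic, unname(nv["pWaic"]), tolerance = 1e-10)
  }
  ## zero-variance matrix: pWAIC exactly 0, WAIC = -2c
  ll0 <- matrix(-2.5, 6, 3)
  w0 <- waic(ll0)
  expect_identical(w0$pWaic, 0)
  expect_equal(w0$waic, -2 * 3 * -2.5)
  expect_error(waic(matrix(0, 1, 3)), "2 draws")
  expect_error(waic(matrix(0, 5, 3), mask = rep(FALSE, 3)), "empty")
})

test_that("WAIC is additive over disjoint cells and draw-order invariant", {
  set.seed(32)
  ll <- matrix(rnorm(8 * 6, -2, 0.5), 8, 6)
  whole <- waic(ll)$waic
  parts <- waic(ll, 1:3)$waic + waic(ll, 4:6)$waic
  expect_equal(whole, parts, tolerance = 1e-10)
  perm <- sample(8)
  expect_equal(waic(ll[perm, ])$waic, whole, tolerance = 1e-10)
})

test_that("MSPE matches hand arithmetic and the naive loop", {
  y <- c(0); yr <- matrix(c(1, 3), 2, 1)
  expect_equal(mspe(yr, y), (1 + 9) / 2)         # = 5
  set.seed(33)
  yr <- matrix(rpois(40, 6), 5, 8); y <- rpois(8, 6)
  acc <- 0
  for (s in 1:5) for (cc in 1:8) acc <- acc + (yr[s, cc] - y[cc])^2
  expect_equal(mspe(yr, y), acc / 40, tolerance = 1e-12)
  ## plug-in form scores the posterior-mean prediction
  expect_equal(mspe(yr, y, plugin = TRUE), mean((colMeans(yr) - y)^2))
  ## DIC alternative: zero-variance deviance gives pD = 0
  d <- dic(matrix(-1.5, 4, 3))
  expect_equal(d$pD, 0)
  expect_equal(d$dic, 2 * 3 * 1.5)
  ## perfect prediction and guards
  expect_equal(mspe(matrix(rep(y, each = 5), 5, 8), y), 0)
  expect_equal(mspe(yr[, c(3, 1, 2)], y[c(3, 1, 2)]), mspe(yr, y, mask = 1:3))
  expect_error(mspe(yr, y, mask = integer(0)), "empty")
  expect_error(mspe(yr, y[1:3]), "align")
})

test_that("fit tables decompose by disease and year window", {
  spec <- modelSpec("Alt1", 2)
  ds <- syntheticDataset(spec, 3, 3, 6, seed = 13)
  f <- recomputeExpected(ds$frame)
  fit <- runMcmc(f, ds$graph, ds$cov, spec,
                 mcmcConfig(nChains = 1, nBurnin = 100, nSamples = 80, seed = 1))
  yrs <- studyYears(f)
  wins <- list(full = range(yrs), early = c(yrs[1], yrs[3]),
               late = c(yrs[4], yrs[6]))
  tab <- fitTable(fit, f, windows = wins)
  expect_setequal(unique(tab$disease), c("D1", "D2", "all"))
  pick <- function(m, d, w) tab$value[tab$measure == m & tab$disease == d &
                                      tab$window == w]
  ## per-disease WAIC sums to the all-disease WAIC (additivity)
  expect_equal(pick("WAIC", "D1", "full") + pick("WAIC", "D2", "full"),
               pick("WAIC", "all", "full"), tolerance = 1e-8)
  ## early + late partition the full window
  expect_equal(pick("WAIC", "all", "early") + pick("WAIC", "all", "late"),
               pick("WAIC", "all", "full"), tolerance = 1e-8)
  ## single full window, K = 1 mask equals calling waic/mspe directly
  m1 <- cellIndex(fit)$disease == "D1"
  expect_equal(pick("WAIC", "D1", "full"),
               waic(pointwiseLogLik(fit), m1)$waic)
  expect_equal(pick("MSPE", "D1", "full"),
               mspe(yRep(fit), as.vector(counts(f)), m1))
  expect_error(fitTable(fit, f, windows = list(bad = c(1890, 1900))),
               "outside")
  ## pretty printer reshapes without dropping values
  out <- capture.output(wide <- printFitTable(tab))
  expect_equal(nrow(wide), 9)
  expect_true(any(grepl("WAIC", out)))
})

test_that("total random component summary matches an independent loop", {
  spec <- modelSpec("Alt2", 1)
  ds <- syntheticDataset(spec, 2, 2, 3, seed = 23)
  f <- recomputeExpected(ds$frame)
  fit <- runMcmc(f, ds$graph, ds$cov, spec,
                 mcmcConfig(nChains = 1, nBurnin = 120, nSamples = 60, seed = 2))
  rc <- randomComponentSummary(fit)
  X <- drawMatrix(fit)
  idx <- cellIndex(fit)
  for (cc in sample(nrow(idx), 5)) {
    i <- idx$i[cc]; j <- idx$j[cc]
    tot <- numeric(nrow(X))
    for (s in seq_len(nrow(X))) {
      q <- sapply(1:3, function(h)
        plogis(X[s, sprintf("mixZ[%d,1,%d]", i, h)] +
               X[s, sprintf("mixA[%d,1,%d]", i, h)]))
      p <- q / sum(q)
      tot[s] <- p[1] * (X[s, sprintf("u[%d,1]", i)] + X[s, sprintf("v[%d]", i)]) +
        p[2] * X[s, sprintf("gamma[%d]", j)] +
        p[3] * X[s, sprintf("phi[%d,%d,1]", i, j)]
    }
    expect_equal(rc$summary$mean[cc], mean(tot), tolerance = 1e-10)
  }
  expect_true(all(abs(rc$weights$pS + rc$weights$pT + rc$weights$pST - 1) < 1e-12))
})

test_that("zero random effects give a zero component; weights report variance shares", {
  ## hand-built Alt2 draws: all effects zero except fixed mixture logits
  spec <- modelSpec("Alt2", 1)
  f <- addExpectedCounts(toyFrame(1, 1, 1, counts = array(3, c(1, 1, 1))))
  st <- initializeState(spec, f)
  st$mixA[1, 1, ] <- qlogis(c(0.1, 0.5, 0.4))
  nm <- stmixmap:::.flattenNames(spec, st)
  draws <- matrix(rep(stmixmap:::.flattenValues(st), each = 2), 2,
                  dimnames = list(NULL, nm))
  s <- fakeSamples(draws, c(1, 1), spec = spec,
                   cellIndex = data.frame(i = 1, j = 1, k = 1, county = "A",
                                          year = 2000, disease = "D1"))
  rc <- randomComponentSummary(s)
  expect_equal(rc$summary$mean, 0)
  expect_equal(rc$weights$pS, 0.1, tolerance = 1e-12)
  expect_equal(rc$weights$pT, 0.5, tolerance = 1e-12)
  expect_equal(rc$weights$pST, 0.4, tolerance = 1e-12)
  expect_equal(rc$weights$varianceShare, "S 10% / T 50% / ST 40%")
})
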