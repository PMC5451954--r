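## Fixture builders shared across the test files.  Everything is
## generated in code; no data files.

toyFrame <- function(I = 2L, J = 2L, K = 1L, counts = NULL, pops = NULL,
                     coded = NULL) {
  if (is.null(counts)) counts <- array(seq_len(I * J * K), c(I, J, K))
  if (is.null(pops)) pops <- matrix(1e4 + 1e3 * seq_len(I), I, J)
  studyFrame(LETTERS[seq_len(I)], 2000L + seq_len(J) - 1L,
             paste0("D", seq_len(K)), counts, pops, coded = coded)
}

randomFrame <- function(seed, I = 3L, J = 4L, K = 2L) {
  set.seed(seed)
  counts <- array(rpois(I * J * K, 20), c(I, J, K))
  pops <- matrix(round(runif(I * J, 1e4, 1e5)), I, J)
  coded <- array(runif(I * J * K) < 0.2, c(I, J, K))
  counts[coded] <- 5L  # a valid censoring code
  studyFrame(paste0("c", seq_len(I)), 1996L + seq_len(J) - 1L,
             paste0("D", seq_len(K)), counts, pops, coded = coded)
}

## hand-rolled straight-line evaluation of every variant's predictor;
## intentionally independent of the package's vectorized implementation
naivePredictor <- function(spec, st, cov, I, J, K) {
  out <- array(0, c(I, J, K))
  for (i in seq_len(I)) for (j in seq_len(J)) for (k in seq_len(K)) {
    Xs <- if (ncol(cov@spatial)) sum(cov@spatial[i, ] * st$betaS[, k]) else 0
    Xt <- if (ncol(cov@temporal)) sum(cov@temporal[j, ] * st$betaT[, k]) else 0
    jb <- min(j, dim(st$betaST)[2])
    Xst <- if (dim(cov@spacetime)[3])
      sum(cov@spacetime[i, j, ] * st$betaST[, jb, k]) else 0
    MS <- Xs + st$u[i, k] + st$v[i]
    g <- switch(spec@variant,
      F2PRED = st$gamma[j, 1], Alt2 = st$gamma[j, 1],
      Alt1 = if (ncol(st$gamma) > 1) st$gamma[j, k] else st$gamma[j, 1],
      Alt3a = st$rho[k] * st$gamma[j, 1],
      Alt3b = sign(st$gamma[j, 1]) * abs(st$gamma[j, 1])^st$rho[k])
    if (spec@variant == "Alt2") {
      q <- plogis(st$mixZ[i, k, ] + st$mixA[i, k, ])
      p <- q / sum(q)
      out[i, j, k] <- st$alpha0[k] + p[1] * MS + p[2] * (Xt + g) +
        p[3] * (Xst + st$phi[i, j, k])
    } else {
      p <- plogis(st$mixZ[i, k, 1] + st$mixA[i, k, 1])
      out[i, j, k] <- st$alpha0[k] + p * MS +
        (1 - p) * (Xst + Xt + g + st$phi[i, j, k])
    }
  }
  out
}

## a minimal PosteriorSamples built by hand from a draw matrix, for
## tests of diagnostics/summaries that should not need a real fit
fakeSamples <- function(draws, chain, spec = modelSpec("Alt1", 1),
                        cellIndex = NULL, pwll = NULL, yrep = NULL) {
  if (is.null(pwll)) pwll <- matrix(0, nrow(draws), 0)
  if (is.null(yrep)) yrep <- matrix(0L, nrow(draws), 0)
  if (is.null(cellIndex)) cellIndex <- data.frame()
  new("PosteriorSamples", draws = draws, chain = as.integer(chain),
      pointwiseLogLik = pwll, yRep = yrep, cellIndex = cellIndex,
      acceptance = list(), proposalScales = list(), spec = spec,
      config = mcmcConfig(nChains = length(unique(chain)), nBurnin = 1L,
                          nSamples = nrow(draws)))
}

## batch-means Monte Carlo SE of a chain's mean
batchMcse <- function(x, nBatches = 20L) {
  bm <- tapply(x, cut(seq_along(x), nBatches, labels = FALSE), mean)
  sd(bm) / sqrt(length(bm))
}

## joint intrinsic-CAR log kernel (pairwise-difference form), used as
## the reference in the full-conditional consistency checks
icarJointKernel <- function(x, tau, graph) {
  s <- 0
  for (i in seq_along(x)) for (l in neighbors(graph)[[i]])
    if (i < l) s <- s + (x[i] - x[l])^2
  -tau / 2 * s
}
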