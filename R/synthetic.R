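## synthetic_data module: lattice worlds with known mixture structure.
##
## Generates multi-disease count panels from the model family itself so
## every other module can be exercised end-to-end without any external
## data: a rook-adjacency grid of counties, log-uniform county
## populations, Poisson counts with mean e * theta(true state), and the
## provider-style small-count thresholding.

#' Rook-adjacency lattice graph
#'
#' @param rows,cols grid dimensions; rows * cols >= 2.
#' @return an \code{\linkS4class{AdjacencyGraph}}; corner nodes have 2
#'   neighbors, edge nodes 3, interior nodes 4.
#' @export
makeLattice <- function(rows, cols) {
  if (rows * cols < 2L)
    .stopf("a %dx%d lattice has an isolated node; need rows*cols >= 2",
           rows, cols)
  id <- function(r, c) (r - 1L) * cols + c
  edges <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) edges[[length(edges) + 1L]] <- c(id(r, c), id(r, c + 1L))
    if (r < rows) edges[[length(edges) + 1L]] <- c(id(r, c), id(r + 1L, c))
  }
  ids <- sprintf("C%03d", seq_len(rows * cols))
  em <- do.call(rbind, edges)
  em <- rbind(em, em[, 2:1])    # both directions: already symmetric
  adjacencyGraph(ids, cbind(ids[em[, 1]], ids[em[, 2]]))
}

## sample a centered intrinsic-CAR field (generalized-inverse sampling
## via the eigendecomposition of the graph Laplacian)
.sampleICAR <- function(graph, sd) {
  I <- length(graph@countyIds)
  W <- matrix(0, I, I)
  for (i in seq_len(I)) W[i, graph@neighbors[[i]]] <- 1
  Q <- diag(graph@nNeighbors) - W
  eig <- eigen(Q, symmetric = TRUE)
  pos <- eig$values > 1e-8
  x <- eig$vectors[, pos, drop = FALSE] %*%
    (stats::rnorm(sum(pos)) / sqrt(eig$values[pos])) * sd
  as.vector(x - mean(x))
}

## sample a centered RW1 path of length J
.sampleRW1 <- function(J, sd) {
  if (J == 1L) return(0)
  g <- cumsum(c(0, stats::rnorm(J - 1L, 0, sd)))
  g - mean(g)
}

#' Default signal settings for the generator
#'
#' The defaults state a moderately spatial world: the correlated
#' spatial effect dominates the uncorrelated one (as is typical for
#' fitted disease-mapping models), the temporal walk drifts visibly,
#' and the spatio-temporal interaction is small noise.  Mixture logits
#' are centered (equal prior weights) unless a location is given.
#'
#' @param ... overrides of any default entry.
#' @return named list of signal settings.
#' @export
signalSettings <- function(...) {
  out <- list(alpha0 = 0, betaS = numeric(0), betaT = numeric(0),
              betaST = numeric(0), sdU = 0.1, sdV = 0.4, sdGamma = 0.25,
              sdPhi = 0.1, sdZ = 0.75, sdMixA = 0.75, mixLogitMean = 0,
              rho = NULL)
  ov <- list(...)
  out[names(ov)] <- ov
  out
}

#' Draw a true parameter state from the generative priors
#'
#' v and z from centered intrinsic CAR fields, gamma from a centered
#' RW1, u / phi / a iid normal, rho from its prior (unless fixed in the
#' settings), fixed effects at the user-stated values.
#'
#' @param spec a \code{ModelSpec}.
#' @param graph an \code{AdjacencyGraph}.
#' @param J number of years.
#' @param seed integer seed.
#' @param signal a \code{\link{signalSettings}} list.
#' @param cov optional \code{CovariateSet} fixing covariate dimensions;
#'   defaults to the lengths of the beta entries in \code{signal}.
#' @return a parameter state (see \code{\link{initializeState}}).
#' @export
sampleTrueState <- function(spec, graph, J, seed = 1L,
                            signal = signalSettings(), cov = NULL) {
  set.seed(as.integer(seed))
  I <- length(graph@countyIds); K <- spec@nDiseases
  Ps <- length(signal$betaS); Pt <- length(signal$betaT)
  Pst <- length(signal$betaST)
  Jb <- if (spec@timeVaryingBetaST) J else 1L
  Kg <- .nGammaCols(spec)
  H <- if (spec@variant == "Alt2") 3L else 1L
  mlm <- rep_len(signal$mixLogitMean, H)
  state <- list(
    alpha0 = rep_len(signal$alpha0, K),
    betaS = matrix(signal$betaS, Ps, K),
    betaT = matrix(signal$betaT, Pt, K),
    betaST = array(rep(signal$betaST, Jb * K), c(Pst, Jb, K)),
    u = matrix(stats::rnorm(I * K, 0, signal$sdU), I, K),
    v = .sampleICAR(graph, signal$sdV),
    gamma = matrix(replicate(Kg, .sampleRW1(J, signal$sdGamma)), J, Kg),
    phi = array(stats::rnorm(I * J * K, 0, signal$sdPhi), c(I, J, K)),
    mixZ = array(0, c(I, K, H)), mixA = array(0, c(I, K, H)),
    rho = numeric(0),
    sigma = list())
  for (k in seq_len(K)) for (h in seq_len(H)) {
    state$mixZ[, k, h] <- if (signal$sdZ > 0) .sampleICAR(graph, signal$sdZ)
                          else numeric(I)
    state$mixA[, k, h] <- stats::rnorm(I, mlm[h], signal$sdMixA)
  }
  if (spec@variant %in% c("Alt3a", "Alt3b")) {
    state$rho <- if (!is.null(signal$rho)) rep_len(signal$rho, K)
    else if (spec@variant == "Alt3a") stats::rnorm(K, 0, 1)
    else stats::rgamma(K, 2, 1)
  }
  state$sigma <- list(intercept = 1, beta = 1,
                      u = rep(max(signal$sdU, 1e-3), K),
                      v = max(signal$sdV, 1e-3),
                      gamma = max(signal$sdGamma, 1e-3),
                      phi = rep(max(signal$sdPhi, 1e-3), K),
                      z = rep(max(signal$sdZ, 1e-3), K),
                      mixA = rep(max(signal$sdMixA, 1e-3), K))
  if (spec@variant == "Alt3a") state$sigma$rho <- rep(1, K)
  state
}

#' Generate Poisson counts from a true state
#'
#' \eqn{y_{ijk} \sim \mathrm{Pois}(e_{ijk}\,\theta_{ijk})} with
#' \eqn{e_{ijk} = \mathrm{rate}_k \cdot n_{ij}} and \eqn{\theta} from
#' the variant's predictor at the true state.
#'
#' @param spec a \code{ModelSpec}.
#' @param state a true parameter state.
#' @param populations length-I vector or I x J matrix of populations.
#' @param cov a \code{CovariateSet}.
#' @param rates per-disease overall rates.
#' @param seed integer seed.
#' @param countyIds,years,diseaseIds optional labels.
#' @return a \code{StudyFrame} with true counts and the generating
#'   expected counts attached.
#' @export
generateCounts <- function(spec, state, populations, cov, rates, seed = 1L,
                           countyIds = NULL, years = NULL, diseaseIds = NULL) {
  set.seed(as.integer(seed))
  I <- nrow(state$u); J <- dim(state$phi)[2]; K <- spec@nDiseases
  if (is.vector(populations)) populations <- matrix(populations, I, J)
  if (length(rates) != K) .stopf("need one rate per disease")
  countyIds <- countyIds %||% sprintf("C%03d", seq_len(I))
  years <- years %||% (1995L + seq_len(J))
  diseaseIds <- diseaseIds %||% paste0("D", seq_len(K))
  lt <- .linearPredictor(spec, state, cov, I, J, K)
  e <- array(NA_real_, c(I, J, K))
  for (k in seq_len(K)) e[, , k] <- rates[k] * populations
  mu <- e * exp(lt)
  if (any(!is.finite(mu)) || any(mu > 1e9)) {
    bad <- which(!is.finite(mu) | mu > 1e9, arr.ind = TRUE)[1, ]
    .stopf("Poisson mean overflow at cell (%d,%d,%d): theta = %.3g",
           bad[1], bad[2], bad[3], exp(lt[bad[1], bad[2], bad[3]]))
  }
  y <- array(stats::rpois(I * J * K, mu), c(I, J, K))
  studyFrame(countyIds, years, diseaseIds, y, populations, expected = e)
}

#' Apply provider-style small-count thresholding
#'
#' True counts inside a scheme interval are replaced by the interval's
#' code and flagged; zeros and counts outside all intervals pass through
#' unchanged.  The expected counts are cleared: the censored data
#' pipeline must recompute them from the coded values.
#'
#' @param frame a \code{StudyFrame} of true counts.
#' @param scheme a \code{ThresholdScheme}.
#' @return the coded \code{StudyFrame}.
#' @export
applyThresholding <- function(frame, scheme = defaultThresholdScheme()) {
  stopifnot(is(frame, "StudyFrame"), is(scheme, "ThresholdScheme"))
  counts <- frame@counts
  coded <- array(FALSE, dim(counts))
  for (r in seq_along(scheme@codes)) {
    inr <- counts >= scheme@lower[r] & counts <= scheme@upper[r] & !coded
    counts[inr] <- scheme@codes[r]
    coded[inr] <- TRUE
  }
  frame@counts <- counts
  frame@coded <- coded
  frame@expected <- array(NA_real_, dim(counts))
  frame@imputed <- FALSE
  frame
}

#' Default per-disease overall rates
#'
#' 1e-4 / 3e-4 / 8e-4 per person-year (ordered rare to common),
#' matching the magnitudes of the motivating study's three cancers so
#' that small-count censoring occurs at realistic frequencies.
#'
#' @param K number of diseases.
#' @return numeric vector of length K.
#' @export
defaultRates <- function(K) c(1e-4, 3e-4, 8e-4)[seq_len(K)]

#' Simulate a complete synthetic dataset bundle
#'
#' Builds the lattice, populations (log-uniform between 1e4 and 5e5),
#' iid standard-normal covariates, a true state, true counts, and the
#' threshold-coded version of the counts.
#'
#' @param spec a \code{ModelSpec}.
#' @param rows,cols lattice dimensions.
#' @param J number of years.
#' @param seed master seed.
#' @param signal a \code{\link{signalSettings}} list.
#' @param rates per-disease rates (default \code{defaultRates}).
#' @param scheme a \code{ThresholdScheme}.
#' @param popRange population range (log-uniform).
#' @return list(frame, codedFrame, graph, cov, state, rates, spec, seed)
#' @export
syntheticDataset <- function(spec, rows = 8L, cols = 8L, J = 10L, seed = 1L,
                             signal = signalSettings(),
                             rates = defaultRates(spec@nDiseases),
                             scheme = defaultThresholdScheme(),
                             popRange = c(1e4, 5e5)) {
  graph <- makeLattice(rows, cols)
  I <- rows * cols
  set.seed(.childSeed(seed, 101L))
  populations <- round(exp(stats::runif(I, log(popRange[1]), log(popRange[2]))))
  Ps <- length(signal$betaS); Pt <- length(signal$betaT)
  Pst <- length(signal$betaST)
  cov <- covariateSet(
    spatial = if (Ps) matrix(stats::rnorm(I * Ps), I, Ps) else NULL,
    temporal = if (Pt) matrix(stats::rnorm(J * Pt), J, Pt) else NULL,
    spacetime = if (Pst) array(stats::rnorm(I * J * Pst), c(I, J, Pst)) else NULL,
    I = I, J = J)
  if (Ps + Pt + Pst > 0) cov <- standardizeCovariates(cov)
  state <- sampleTrueState(spec, graph, J, seed = .childSeed(seed, 202L),
                           signal = signal, cov = cov)
  frame <- generateCounts(spec, state, populations, cov, rates,
                          seed = .childSeed(seed, 303L))
  codedFrame <- applyThresholding(frame, scheme)
  list(frame = frame, codedFrame = codedFrame, graph = graph, cov = cov,
       state = state, rates = rates, spec = spec, scheme = scheme, seed = seed)
}

#' Simulate-fit-recover harness
#'
#' Per replicate: simulate a dataset, optionally threshold and impute
#' it, fit the model, and record credible-interval coverage of the
#' fixed effects, correlation of the recovered temporal walk with the
#' truth, the share of counties whose posterior mean spatial weight
#' exceeds the spatio-temporal one, and (optionally) WAIC for
#' alternative variants fit to the same data.
#'
#' @param spec the generating \code{ModelSpec}.
#' @param signal a \code{\link{signalSettings}} list.
#' @param config a scaled \code{McmcConfig}.
#' @param nReplicates number of replicates.
#' @param seed master seed.
#' @param rows,cols,J grid size (desk scale: <= 10 x 10, J <= 12).
#' @param threshold apply thresholding + imputation before fitting.
#' @param compareVariants optional character vector of additional
#'   variants to fit for WAIC comparison.
#' @return data.frame, one row per replicate; non-convergent replicates
#'   are flagged in the \code{converged} column, never dropped.
#' @export
recoveryHarness <- function(spec, signal = signalSettings(),
                            config = mcmcConfig(nChains = 1L, nBurnin = 500L,
                                                nSamples = 500L),
                            nReplicates = 1L, seed = 1L, rows = 6L, cols = 6L,
                            J = 8L, threshold = TRUE, compareVariants = NULL) {
  out <- list()
  for (r in seq_len(nReplicates)) {
    ds <- syntheticDataset(spec, rows, cols, J,
                           seed = .childSeed(seed, 1000L + r), signal = signal)
    frame <- if (threshold) {
      f <- addExpectedCounts(ds$codedFrame)
      f <- imputeThresholded(f, ds$scheme, seed = .childSeed(seed, 2000L + r))
      recomputeExpected(f)
    } else recomputeExpected(ds$frame)
    cfg <- mcmcConfig(nChains = config@nChains, nBurnin = config@nBurnin,
                      nSamples = config@nSamples, thin = config@thin,
                      seed = .childSeed(seed, 3000L + r),
                      adaptEvery = config@adaptEvery,
                      recenter = config@recenter)
    fit <- runMcmc(frame, ds$graph, ds$cov, spec, cfg)
    row <- list(rep = r)
    row$converged <- if (cfg@nChains >= 2L) gelmanRubin(fit)$converged else NA
    covg <- function(fam, true) {
      if (!length(true)) return(NA)
      dr <- paramDraws(fit, fam)
      all(vapply(seq_along(true), function(p) {
        q <- stats::quantile(dr[, p], c(0.025, 0.975))
        true[p] >= q[1] && true[p] <= q[2]
      }, logical(1)))
    }
    row$betaSCovered <- covg("betaS", as.vector(ds$state$betaS))
    row$betaTCovered <- covg("betaT", as.vector(ds$state$betaT))
    ghat <- colMeans(paramDraws(fit, "gamma"))
    gtrue <- as.vector(ds$state$gamma)
    row$gammaCorr <- if (stats::sd(gtrue) > 0 && stats::sd(ghat) > 0)
      stats::cor(ghat[seq_along(gtrue)], gtrue) else NA
    w <- randomComponentSummary(fit)$weights
    row$shareSpatialPreferred <- mean(w$pS > w$pST)
    if (!is.null(compareVariants)) {
      for (vv in compareVariants) {
        sp2 <- modelSpec(vv, spec@nDiseases,
                         timeVaryingBetaST = spec@timeVaryingBetaST)
        fit2 <- runMcmc(frame, ds$graph, ds$cov, sp2, cfg)
        row[[paste0("waic.", vv)]] <- waic(fit2)$waic
      }
      row$waic.self <- waic(fit)$waic
    }
    out[[r]] <- as.data.frame(row)
  }
  do.call(rbind, out)
}
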