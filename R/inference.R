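## inference module: adaptive Metropolis-within-Gibbs sampler.
##
## No conjugate Gibbs steps exist under the Poisson likelihood with
## Unif(0,C) priors on the SDs, so every block uses Gaussian random-walk
## Metropolis proposals with scales adapted toward a target acceptance
## rate during burn-in only (frozen afterwards, preserving the
## stationary law).  Single-site updates of the CAR fields (v, z) and
## the random walk (gamma) are batched by graph coloring: sites of one
## color are conditionally independent given the rest, so their
## accept/reject decisions can be made simultaneously and vectorized.
## SDs are updated on the log scale with the Jacobian, and rejected
## outside their (0, C) support.

#' Construct an McmcConfig
#'
#' Defaults follow the published analysis (2 chains, 45,000 burn-in,
#' 5,000 retained samples); tests and examples use much shorter runs.
#'
#' @param nChains,nBurnin,nSamples,thin run-length settings.
#' @param seed master integer seed; all randomness derives from it.
#' @param adaptEvery adaptation batch length during burn-in.
#' @param targetAccept target Metropolis acceptance rate.
#' @param recenter sum-to-zero recentering of v / gamma / z each sweep.
#' @param randomizeOrder permute block update order each sweep.
#' @param priorOnly switch the likelihood off (sampler validation).
#' @param verbose print progress.
#' @return an \code{\linkS4class{McmcConfig}}
#' @export
mcmcConfig <- function(nChains = 2L, nBurnin = 45000L, nSamples = 5000L,
                       thin = 1L, seed = 1L, adaptEvery = 50L,
                       targetAccept = 0.44, recenter = TRUE,
                       randomizeOrder = FALSE, priorOnly = FALSE,
                       verbose = FALSE) {
  new("McmcConfig", nChains = as.integer(nChains),
      nBurnin = as.integer(nBurnin), nSamples = as.integer(nSamples),
      thin = as.integer(thin), seed = as.integer(seed),
      adaptEvery = as.integer(adaptEvery), targetAccept = targetAccept,
      recenter = recenter, randomizeOrder = randomizeOrder,
      priorOnly = priorOnly, verbose = verbose)
}

#' Deterministic initialization of a parameter state
#'
#' Intercepts start at log(sum y / sum e) per disease; all random
#' effects, fixed effects and mixture logits start at 0 (equal mixture
#' weights); SDs start at C/2; Alt3 scaling parameters start at their
#' prior mean.
#'
#' @param spec a \code{ModelSpec}.
#' @param frame a \code{StudyFrame} with expected counts.
#' @param graph an \code{AdjacencyGraph} (unused, kept for symmetry).
#' @param cov a \code{CovariateSet} or NULL.
#' @return a parameter state (named list; see Details).
#' @details The state is a plain named list with elements
#'   \code{alpha0} (K), \code{betaS} (P_S x K), \code{betaT} (P_T x K),
#'   \code{betaST} (P_ST x J* x K, J* = J or 1), \code{u} (I x K),
#'   \code{v} (I), \code{gamma} (J x K* with K* = K for multi-disease
#'   Alt1, else 1), \code{phi} (I x J x K), \code{mixZ} and \code{mixA}
#'   (I x K x H, H = 3 for Alt2 else 1), \code{rho} (K, Alt3 only) and
#'   \code{sigma} (named list of SDs per effect family).
#' @export
initializeState <- function(spec, frame, graph = NULL, cov = NULL) {
  d <- dim(frame); I <- d[1]; J <- d[2]; K <- d[3]
  if (K != spec@nDiseases)
    .stopf("frame has %d disease(s) but spec expects %d", K, spec@nDiseases)
  if (is.null(cov)) cov <- covariateSet(I = I, J = J)
  Ps <- ncol(cov@spatial); Pt <- ncol(cov@temporal)
  Pst <- dim(cov@spacetime)[3]
  Jb <- if (spec@timeVaryingBetaST) J else 1L
  Kg <- .nGammaCols(spec)
  H <- if (spec@variant == "Alt2") 3L else 1L
  alpha0 <- vapply(seq_len(K), function(k) {
    e <- if (hasExpectedCounts(frame)) sum(frame@expected[, , k]) else 1
    log(max(sum(frame@counts[, , k]), 0.5) / max(e, 1e-12))
  }, numeric(1))
  fams <- if (spec@interceptOnly) "intercept" else .sdFamilies(spec)
  sigma <- list()
  for (fam in fams) {
    len <- if (fam %in% c("u", "phi", "z", "mixA", "rho")) K else 1L
    val <- if (fam %in% names(spec@fixedSd)) spec@fixedSd[[fam]]
           else .getC(spec, fam) / 2
    sigma[[fam]] <- rep(val, len)
  }
  rho <- if (spec@variant == "Alt3a") rep(0, K)
         else if (spec@variant == "Alt3b") rep(2, K) else numeric(0)
  list(alpha0 = alpha0,
       betaS = matrix(0, Ps, K), betaT = matrix(0, Pt, K),
       betaST = array(0, c(Pst, Jb, K)),
       u = matrix(0, I, K), v = numeric(I),
       gamma = matrix(0, J, Kg),
       phi = array(0, c(I, J, K)),
       mixZ = array(0, c(I, K, H)), mixA = array(0, c(I, K, H)),
       rho = rho, sigma = sigma)
}

## flat parameter vector + (once) its labels; order must stay in sync
.flattenValues <- function(state) {
  c(state$alpha0, state$betaS, state$betaT, state$betaST, state$u, state$v,
    state$gamma, state$phi, state$mixZ, state$mixA, state$rho,
    unlist(state$sigma, use.names = FALSE))
}

.flattenNames <- function(spec, state) {
  idx <- function(nm, ...) {
    dims <- list(...)
    if (!prod(lengths(dims))) return(character(0))
    g <- do.call(expand.grid, dims)
    sprintf("%s[%s]", nm, do.call(paste, c(unname(as.list(g)), sep = ",")))
  }
  K <- length(state$alpha0)
  ## order must match .flattenValues exactly
  nm <- c(idx("alpha0", seq_len(K)),
          idx("betaS", seq_len(nrow(state$betaS)), seq_len(K)),
          idx("betaT", seq_len(nrow(state$betaT)), seq_len(K)),
          idx("betaST", seq_len(dim(state$betaST)[1]),
              seq_len(dim(state$betaST)[2]), seq_len(K)),
          idx("u", seq_len(nrow(state$u)), seq_len(K)),
          idx("v", seq_along(state$v)),
          if (ncol(state$gamma) == 1L) idx("gamma", seq_len(nrow(state$gamma)))
          else idx("gamma", seq_len(nrow(state$gamma)), seq_len(ncol(state$gamma))),
          idx("phi", seq_len(dim(state$phi)[1]), seq_len(dim(state$phi)[2]),
              seq_len(K)),
          if (dim(state$mixZ)[3] == 1L)
            idx("mixZ", seq_len(dim(state$mixZ)[1]), seq_len(K))
          else idx("mixZ", seq_len(dim(state$mixZ)[1]), seq_len(K), 1:3),
          if (dim(state$mixA)[3] == 1L)
            idx("mixA", seq_len(dim(state$mixA)[1]), seq_len(K))
          else idx("mixA", seq_len(dim(state$mixA)[1]), seq_len(K), 1:3),
          idx("rho", seq_along(state$rho)),
          unlist(lapply(names(state$sigma), function(fam) {
            len <- length(state$sigma[[fam]])
            if (len == 1L) paste0("sigma.", fam)
            else sprintf("sigma.%s[%d]", fam, seq_len(len))
          })))
  nm
}

#' Fit a space-time mixture model by MCMC
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler for the given
#' variant.  One sweep updates, in fixed order: intercepts, each fixed-
#' effect block, u, v (recentred), gamma (recentred), phi, the mixture
#' logit fields z and a, the Alt3 scaling parameters, and every SD.
#' Posterior-predictive counts are drawn at every retained iteration.
#' The run is fully reproducible given (spec, config).
#'
#' @param frame an imputed \code{StudyFrame} with expected counts.
#' @param graph an \code{AdjacencyGraph} (NULL allowed for
#'   intercept-only specs).
#' @param cov a standardized \code{CovariateSet}, or NULL for none.
#' @param spec a \code{ModelSpec}.
#' @param config an \code{McmcConfig}.
#' @return a \code{\linkS4class{PosteriorSamples}}
#' @export
runMcmc <- function(frame, graph = NULL, cov = NULL, spec,
                    config = mcmcConfig()) {
  stopifnot(is(frame, "StudyFrame"), is(spec, "ModelSpec"),
            is(config, "McmcConfig"))
  d <- dim(frame); I <- d[1]; J <- d[2]; K <- d[3]
  if (K != spec@nDiseases)
    .stopf("frame has %d disease(s) but spec expects %d", K, spec@nDiseases)
  if (any(frame@coded)) .stopf("frame has coded cells; impute before fitting")
  if (!hasExpectedCounts(frame)) .stopf("expected counts not computed")
  if (is.null(cov)) cov <- covariateSet(I = I, J = J)
  nCov <- ncol(cov@spatial) + ncol(cov@temporal) + dim(cov@spacetime)[3]
  if (nCov > 0 && !cov@standardized)
    .stopf("covariates must be standardized before fitting")
  for (k in seq_len(K))
    if (sum(frame@counts[, , k]) == 0 && !config@priorOnly)
      .stopf("disease '%s' has all-zero counts", frame@diseaseIds[k])
  if (!spec@interceptOnly && is.null(graph))
    .stopf("an adjacency graph is required")

  state0 <- initializeState(spec, frame, graph, cov)
  ll0 <- if (config@priorOnly) 0 else logLikelihood(frame, spec, state0, cov)$total
  lp0 <- logPrior(spec, state0, graph)
  if (!is.finite(ll0 + lp0))
    .stopf("non-finite posterior at initialization (log-lik %.3g, log-prior %.3g)",
           ll0, lp0)

  chains <- lapply(seq_len(config@nChains), function(ch)
    .runChain(frame, graph, cov, spec, config, .childSeed(config@seed, ch)))

  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  colnames(draws) <- .flattenNames(spec, state0)
  pwll <- do.call(rbind, lapply(chains, `[[`, "pw"))
  yrep <- do.call(rbind, lapply(chains, `[[`, "yrep"))
  cellIdx <- expand.grid(i = seq_len(I), j = seq_len(J), k = seq_len(K))
  cellIdx$county <- frame@countyIds[cellIdx$i]
  cellIdx$year <- frame@years[cellIdx$j]
  cellIdx$disease <- frame@diseaseIds[cellIdx$k]
  nPer <- config@nSamples %/% config@thin
  new("PosteriorSamples", draws = draws,
      chain = rep(seq_len(config@nChains), each = nPer),
      pointwiseLogLik = pwll, yRep = yrep, cellIndex = cellIdx,
      acceptance = chains[[1]]$accRates,
      proposalScales = chains[[1]]$scales,
      spec = spec, config = config)
}

## one chain of the sampler; returns draws and pointwise quantities
.runChain <- function(frame, graph, cov, spec, config, seed) {
  set.seed(seed)
  d <- dim(frame); I <- d[1]; J <- d[2]; K <- d[3]
  y <- frame@counts; eArr <- frame@expected
  state <- initializeState(spec, frame, graph, cov)
  priorOnly <- config@priorOnly
  Ps <- ncol(cov@spatial); Pt <- ncol(cov@temporal)
  Pst <- dim(cov@spacetime)[3]
  Jb <- dim(state$betaST)[2]
  Kg <- ncol(state$gamma)
  H <- dim(state$mixZ)[3]
  nbrs <- if (!is.null(graph)) graph@neighbors else NULL
  edges <- if (!is.null(graph)) .graphEdges(graph) else NULL
  rankI <- if (!is.null(graph)) I - .graphComponents(graph) else 0L
  colorsI <- if (!is.null(graph)) .greedyColoring(graph@neighbors) else integer(0)
  colorsJ <- rep_len(1:2, J)
  sg <- state$sigma
  fixed <- names(spec@fixedSd)

  pwOf <- function(st) {
    if (priorOnly) return(array(0, d))
    lt <- .linearPredictor(spec, st, cov, I, J, K)
    pw <- stats::dpois(y, eArr * exp(lt), log = TRUE)
    pw[!is.finite(pw)] <- -Inf
    pw
  }
  pw <- pwOf(state)

  ## proposal scales and acceptance counters, keyed by block family
  sc <- list(alpha0 = rep(0.1, K), betaS = rep(0.1, K), betaT = rep(0.1, K),
             betaST = rep(0.1, K), u = rep(0.1, K), v = 0.1,
             gamma = if (Kg > 1) rep(0.1, K) else 0.1, phi = rep(0.1, K),
             z = rep(0.2, K), mixA = rep(0.2, K), rho = rep(0.1, K),
             sigma = lapply(state$sigma, function(s) rep(0.4, length(s))))
  zero <- function(x) if (is.list(x)) lapply(x, zero) else 0 * x
  accN <- zero(sc); tryN <- zero(sc)
  bump <- function(fam, acc, try, k = NULL) {
    if (is.null(k)) { accN[[fam]] <<- accN[[fam]] + acc; tryN[[fam]] <<- tryN[[fam]] + try }
    else { accN[[fam]][k] <<- accN[[fam]][k] + acc; tryN[[fam]][k] <<- tryN[[fam]][k] + try }
  }

  blocks <- if (spec@interceptOnly) c("alpha0", "sigma") else
    c("alpha0", if (Ps) "betaS", if (Pt) "betaT", if (Pst) "betaST",
      "u", "v", "gamma", "phi", "z", "mixA",
      if (spec@variant %in% c("Alt3a", "Alt3b")) "rho", "sigma")

  icarLocalDelta <- function(x, xP, i, tau) {
    nb <- nbrs[[i]]
    -tau / 2 * (sum((xP[i] - x[nb])^2) - sum((x[i] - x[nb])^2))
  }

  nIter <- config@nBurnin + config@nSamples
  nKeep <- config@nSamples %/% config@thin
  nPar <- length(.flattenValues(state))
  draws <- matrix(NA_real_, nKeep, nPar)
  pwMat <- matrix(NA_real_, nKeep, I * J * K)
  yrMat <- matrix(NA_integer_, nKeep, I * J * K)
  keepRow <- 0L

  for (iter in seq_len(nIter)) {
    order <- if (config@randomizeOrder) sample(blocks) else blocks
    for (b in order) switch(b,
      alpha0 = {
        prop <- state$alpha0 + stats::rnorm(K) * sc$alpha0
        stP <- state; stP$alpha0 <- prop
        pwP <- pwOf(stP)
        dll <- colSums(pwP - pw, dims = 2)
        dpr <- stats::dnorm(prop, 0, sg$intercept, log = TRUE) -
          stats::dnorm(state$alpha0, 0, sg$intercept, log = TRUE)
        acc <- log(stats::runif(K)) < dll + dpr
        if (any(acc)) {
          state$alpha0[acc] <- prop[acc]
          pw[, , acc] <- pwP[, , acc]
        }
        bump("alpha0", acc, 1)
      },
      betaS = {
        prop <- state$betaS +
          matrix(stats::rnorm(Ps * K), Ps, K) %*% diag(sc$betaS, K)
        stP <- state; stP$betaS <- prop
        pwP <- pwOf(stP)
        dll <- colSums(pwP - pw, dims = 2)
        dpr <- colSums(stats::dnorm(prop, 0, sg$beta, log = TRUE) -
                       stats::dnorm(state$betaS, 0, sg$beta, log = TRUE))
        acc <- log(stats::runif(K)) < dll + dpr
        if (any(acc)) {
          state$betaS[, acc] <- prop[, acc]
          pw[, , acc] <- pwP[, , acc]
        }
        bump("betaS", acc, 1)
      },
      betaT = {
        prop <- state$betaT +
          matrix(stats::rnorm(Pt * K), Pt, K) %*% diag(sc$betaT, K)
        stP <- state; stP$betaT <- prop
        pwP <- pwOf(stP)
        dll <- colSums(pwP - pw, dims = 2)
        dpr <- colSums(stats::dnorm(prop, 0, sg$beta, log = TRUE) -
                       stats::dnorm(state$betaT, 0, sg$beta, log = TRUE))
        acc <- log(stats::runif(K)) < dll + dpr
        if (any(acc)) {
          state$betaT[, acc] <- prop[, acc]
          pw[, , acc] <- pwP[, , acc]
        }
        bump("betaT", acc, 1)
      },
      betaST = {
        eps <- array(stats::rnorm(Pst * Jb * K), c(Pst, Jb, K))
        for (k in seq_len(K)) eps[, , k] <- eps[, , k] * sc$betaST[k]
        prop <- state$betaST + eps
        stP <- state; stP$betaST <- prop
        pwP <- pwOf(stP)
        dprCell <- stats::dnorm(prop, 0, sg$beta, log = TRUE) -
          stats::dnorm(state$betaST, 0, sg$beta, log = TRUE)
        if (Jb == 1L) {
          dll <- colSums(pwP - pw, dims = 2)
          dpr <- apply(dprCell, 3, sum)
          acc <- log(stats::runif(K)) < dll + dpr
          if (any(acc)) {
            state$betaST[, , acc] <- prop[, , acc]
            pw[, , acc] <- pwP[, , acc]
          }
          bump("betaST", acc, 1)
        } else {
          dll <- apply(pwP - pw, c(2, 3), sum)             # J x K
          dpr <- apply(dprCell, c(2, 3), sum)
          acc <- matrix(log(stats::runif(J * K)), J, K) < dll + dpr
          for (k in seq_len(K)) {
            js <- which(acc[, k])
            if (length(js)) {
              state$betaST[, js, k] <- prop[, js, k]
              pw[, js, k] <- pwP[, js, k]
            }
          }
          bump("betaST", colMeans(acc), 1)
        }
      },
      u = {
        prop <- state$u + matrix(stats::rnorm(I * K), I, K) %*% diag(sc$u, K)
        stP <- state; stP$u <- prop
        pwP <- pwOf(stP)
        dll <- apply(pwP - pw, c(1, 3), sum)               # I x K
        dpr <- stats::dnorm(prop, 0, rep(sg$u, each = I), log = TRUE) -
          stats::dnorm(state$u, 0, rep(sg$u, each = I), log = TRUE)
        acc <- matrix(log(stats::runif(I * K)), I, K) < dll + dpr
        for (k in seq_len(K)) {
          is <- which(acc[, k])
          if (length(is)) {
            state$u[is, k] <- prop[is, k]
            pw[is, , k] <- pwP[is, , k]
          }
        }
        bump("u", colMeans(acc), 1)
      },
      v = {
        tauV <- 1 / sg$v^2
        for (cls in sort(unique(colorsI))) {
          sel <- which(colorsI == cls)
          vP <- state$v
          vP[sel] <- vP[sel] + stats::rnorm(length(sel)) * sc$v
          stP <- state; stP$v <- vP
          pwP <- pwOf(stP)
          dll <- rowSums(pwP - pw, dims = 1)
          dpr <- vapply(sel, function(i)
            icarLocalDelta(state$v, vP, i, tauV), numeric(1))
          acc <- log(stats::runif(length(sel))) < dll[sel] + dpr
          is <- sel[acc]
          if (length(is)) {
            state$v[is] <- vP[is]
            pw[is, , ] <- pwP[is, , ]
          }
          bump("v", sum(acc), length(sel))
        }
      },
      gamma = {
        tauG <- 1 / sg$gamma^2
        rw1LocalDelta <- function(g, gP, j) {
          s <- 0
          if (j > 1) s <- s + (gP[j] - g[j - 1])^2 - (g[j] - g[j - 1])^2
          if (j < J) s <- s + (g[j + 1] - gP[j])^2 - (g[j + 1] - g[j])^2
          -tauG / 2 * s
        }
        for (cls in 1:2) {
          selJ <- which(colorsJ == cls)
          if (!length(selJ)) next
          gP <- state$gamma
          gP[selJ, ] <- gP[selJ, ] +
            matrix(stats::rnorm(length(selJ) * Kg), length(selJ), Kg) *
            rep(if (Kg > 1) sc$gamma else rep(sc$gamma, Kg), each = length(selJ))
          stP <- state; stP$gamma <- gP
          pwP <- pwOf(stP)
          if (Kg == 1L) {
            dll <- apply(pwP - pw, 2, sum)                 # length J
            dpr <- vapply(selJ, function(j)
              rw1LocalDelta(state$gamma[, 1], gP[, 1], j), numeric(1))
            acc <- log(stats::runif(length(selJ))) < dll[selJ] + dpr
            js <- selJ[acc]
            if (length(js)) {
              state$gamma[js, 1] <- gP[js, 1]
              pw[, js, ] <- pwP[, js, ]
            }
            bump("gamma", sum(acc), length(selJ))
          } else {
            dll <- apply(pwP - pw, c(2, 3), sum)           # J x K
            for (k in seq_len(K)) {
              dpr <- vapply(selJ, function(j)
                rw1LocalDelta(state$gamma[, k], gP[, k], j), numeric(1))
              acc <- log(stats::runif(length(selJ))) < dll[selJ, k] + dpr
              js <- selJ[acc]
              if (length(js)) {
                state$gamma[js, k] <- gP[js, k]
                pw[, js, k] <- pwP[, js, k]
              }
              bump("gamma", sum(acc) / length(selJ), 1, k)
            }
          }
        }
      },
      phi = {
        eps <- array(stats::rnorm(I * J * K), d)
        for (k in seq_len(K)) eps[, , k] <- eps[, , k] * sc$phi[k]
        prop <- state$phi + eps
        stP <- state; stP$phi <- prop
        pwP <- pwOf(stP)
        sgp <- rep(sg$phi, each = I * J)
        dpr <- stats::dnorm(prop, 0, sgp, log = TRUE) -
          stats::dnorm(state$phi, 0, sgp, log = TRUE)
        acc <- array(log(stats::runif(I * J * K)), d) < (pwP - pw) + dpr
        state$phi[acc] <- prop[acc]
        pw[acc] <- pwP[acc]
        bump("phi", apply(acc, 3, mean), 1)
      },
      z = {
        tauZ <- 1 / sg$z^2
        for (h in seq_len(H)) for (cls in sort(unique(colorsI))) {
          sel <- which(colorsI == cls)
          zP <- state$mixZ
          zP[sel, , h] <- zP[sel, , h] +
            matrix(stats::rnorm(length(sel) * K), length(sel), K) *
            rep(sc$z, each = length(sel))
          stP <- state; stP$mixZ <- zP
          pwP <- pwOf(stP)
          dll <- apply(pwP - pw, c(1, 3), sum)             # I x K
          for (k in seq_len(K)) {
            dpr <- vapply(sel, function(i)
              icarLocalDelta(state$mixZ[, k, h], zP[, k, h], i, tauZ[k]),
              numeric(1))
            acc <- log(stats::runif(length(sel))) < dll[sel, k] + dpr
            is <- sel[acc]
            if (length(is)) {
              state$mixZ[is, k, h] <- zP[is, k, h]
              pw[is, , k] <- pwP[is, , k]
            }
            bump("z", sum(acc) / length(sel), 1, k)
          }
        }
      },
      mixA = {
        for (h in seq_len(H)) {
          aP <- state$mixA
          aP[, , h] <- aP[, , h] +
            matrix(stats::rnorm(I * K), I, K) * rep(sc$mixA, each = I)
          stP <- state; stP$mixA <- aP
          pwP <- pwOf(stP)
          dll <- apply(pwP - pw, c(1, 3), sum)
          sga <- rep(sg$mixA, each = I)
          dpr <- stats::dnorm(aP[, , h], 0, sga, log = TRUE) -
            stats::dnorm(state$mixA[, , h], 0, sga, log = TRUE)
          dpr <- matrix(dpr, I, K)
          acc <- matrix(log(stats::runif(I * K)), I, K) < dll + dpr
          for (k in seq_len(K)) {
            is <- which(acc[, k])
            if (length(is)) {
              state$mixA[is, k, h] <- aP[is, k, h]
              pw[is, , k] <- pwP[is, , k]
            }
          }
          bump("mixA", colMeans(acc), 1)
        }
      },
      rho = {
        prop <- state$rho + stats::rnorm(K) * sc$rho
        ok <- if (spec@variant == "Alt3b") prop > 0 else rep(TRUE, K)
        stP <- state; stP$rho <- ifelse(ok, prop, state$rho)
        pwP <- pwOf(stP)
        dll <- colSums(pwP - pw, dims = 2)
        dpr <- if (spec@variant == "Alt3a")
          stats::dnorm(prop, 0, sg$rho, log = TRUE) -
            stats::dnorm(state$rho, 0, sg$rho, log = TRUE)
        else
          stats::dgamma(pmax(prop, 1e-300), 2, 1, log = TRUE) -
            stats::dgamma(state$rho, 2, 1, log = TRUE)
        acc <- ok & (log(stats::runif(K)) < dll + dpr)
        if (any(acc)) {
          state$rho[acc] <- prop[acc]
          pw[, , acc] <- pwP[, , acc]
        }
        bump("rho", acc, 1)
      },
      sigma = {
        for (fam in names(sg)) {
          if (fam %in% fixed) next
          Cf <- .getC(spec, fam)
          for (el in seq_along(sg[[fam]])) {
            s <- sg[[fam]][el]
            sP <- exp(log(s) + stats::rnorm(1) * sc$sigma[[fam]][el])
            okP <- sP > 0 && sP < Cf
            accepted <- FALSE
            if (okP) {
              ks <- .sigmaKernelStats(fam, el, state, spec, edges, rankI, J)
              kern <- function(x) -ks$n * log(x) - ks$ss / (2 * x^2)
              lr <- kern(sP) - kern(s) + log(sP) - log(s)
              if (log(stats::runif(1)) < lr) {
                sg[[fam]][el] <- sP
                accepted <- TRUE
              }
            }
            accN$sigma[[fam]][el] <- accN$sigma[[fam]][el] + accepted
            tryN$sigma[[fam]][el] <- tryN$sigma[[fam]][el] + 1
          }
        }
        state$sigma <- sg
      })

    ## sum-to-zero recentering of the improper fields (WinBUGS
    ## car.normal convention); likelihood-affecting, so refresh pw
    if (config@recenter && !spec@interceptOnly) {
      moved <- FALSE
      m <- mean(state$v)
      if (abs(m) > 0) { state$v <- state$v - m; moved <- TRUE }
      gm <- colMeans(state$gamma)
      if (any(abs(gm) > 0)) {
        state$gamma <- sweep(state$gamma, 2, gm)
        moved <- TRUE
      }
      ## the mixture logit CAR fields are deliberately NOT recentred:
      ## their level is the overall component preference, a direction
      ## the posterior identifies (there is no separate mixture
      ## intercept to absorb it into)
      if (moved) pw <- pwOf(state)
    }

    ## adaptation during burn-in only
    if (iter <= config@nBurnin && iter %% config@adaptEvery == 0L) {
      tune <- function(s, a, t) {
        rate <- ifelse(t > 0, a / t, config@targetAccept)
        pmin(pmax(s * exp(rate - config@targetAccept), 1e-5), 50)
      }
      for (fam in setdiff(names(sc), "sigma"))
        sc[[fam]] <- tune(sc[[fam]], accN[[fam]], tryN[[fam]])
      for (fam in names(sc$sigma))
        sc$sigma[[fam]] <- tune(sc$sigma[[fam]], accN$sigma[[fam]],
                                tryN$sigma[[fam]])
      accN <- zero(accN); tryN <- zero(tryN)
    }

    ## retain post-burn-in draws
    if (iter > config@nBurnin &&
        (iter - config@nBurnin) %% config@thin == 0L) {
      keepRow <- keepRow + 1L
      state$sigma <- sg
      draws[keepRow, ] <- .flattenValues(state)
      if (priorOnly) {
        pwMat[keepRow, ] <- 0
        yrMat[keepRow, ] <- 0L
      } else {
        lt <- .linearPredictor(spec, state, cov, I, J, K)
        mu <- eArr * exp(lt)
        pwMat[keepRow, ] <- as.vector(stats::dpois(y, mu, log = TRUE))
        yrMat[keepRow, ] <- stats::rpois(I * J * K, as.vector(mu))
      }
    }
  }

  rate <- function(a, t) ifelse(t > 0, a / t, NA_real_)
  accRates <- list()
  for (fam in setdiff(names(sc), "sigma"))
    accRates[[fam]] <- rate(accN[[fam]], tryN[[fam]])
  list(draws = draws[seq_len(keepRow), , drop = FALSE],
       pw = pwMat[seq_len(keepRow), , drop = FALSE],
       yrep = yrMat[seq_len(keepRow), , drop = FALSE],
       accRates = accRates, scales = sc)
}

## sufficient statistics (effective count, sum of squares) for the
## conditional kernel of one SD parameter
.sigmaKernelStats <- function(fam, el, state, spec, edges, rankI, J) {
  switch(fam,
    intercept = list(n = length(state$alpha0), ss = sum(state$alpha0^2)),
    beta = {
      b <- c(state$betaS, state$betaT, state$betaST)
      list(n = length(b), ss = sum(b^2))
    },
    u = list(n = nrow(state$u), ss = sum(state$u[, el]^2)),
    v = list(n = rankI,
             ss = sum((state$v[edges[, 1]] - state$v[edges[, 2]])^2)),
    gamma = {
      Kg <- ncol(state$gamma)
      list(n = (J - 1) * Kg, ss = sum(diff(state$gamma)^2))
    },
    phi = list(n = dim(state$phi)[1] * dim(state$phi)[2],
               ss = sum(state$phi[, , el]^2)),
    z = {
      H <- dim(state$mixZ)[3]
      ss <- 0
      for (h in seq_len(H)) {
        zk <- state$mixZ[, el, h]
        ss <- ss + sum((zk[edges[, 1]] - zk[edges[, 2]])^2)
      }
      list(n = rankI * H, ss = ss)
    },
    mixA = {
      H <- dim(state$mixA)[3]
      list(n = dim(state$mixA)[1] * H, ss = sum(state$mixA[, el, ]^2))
    },
    rho = list(n = 1, ss = state$rho[el]^2),
    .stopf("unknown SD family '%s'", fam))
}

#' Gelman-Rubin potential scale reduction
#'
#' Classic (non-split) PSRF per parameter across chains:
#' \eqn{\hat R = \sqrt{((n-1)/n\,W + B/n) / W}}.  With a single chain
#' the statistic is undefined and an error is raised.  Two bit-identical
#' chains give the no-between-variance limit \eqn{\sqrt{(n-1)/n}}.
#'
#' @param samples a \code{PosteriorSamples} with >= 2 chains.
#' @param parameter optional column name (or regular prefix like "v");
#'   NULL computes all.
#' @return list(rhat = named vector, converged = max(rhat) < 1.1)
#' @export
gelmanRubin <- function(samples, parameter = NULL) {
  stopifnot(is(samples, "PosteriorSamples"))
  ch <- samples@chain
  if (length(unique(ch)) < 2L)
    .stopf("Gelman-Rubin diagnostic requires at least 2 chains")
  X <- samples@draws
  if (!is.null(parameter)) {
    cols <- if (all(parameter %in% colnames(X))) parameter
            else colnames(paramDraws(samples, parameter))
    X <- X[, cols, drop = FALSE]
  }
  rhat <- apply(X, 2, function(x) .psrf(split(x, ch)))
  list(rhat = rhat, converged = all(is.na(rhat) | rhat < 1.1))
}

.psrf <- function(chains) {
  m <- length(chains); n <- length(chains[[1]])
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}
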