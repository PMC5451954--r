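## model_family module: the five space-time mixture variants.
##
## Log relative risk: log(theta_ijk) = alpha_0k + sum_h p_ikh M_ijkh,
## with county-level mixture weights p built from a CAR-correlated logit
## field z and an uncorrelated logit field a.  Variants:
##   F2PRED : h = {S, ST}; temporal walk gamma_j shared across diseases.
##   Alt1   : h = {S, ST}; disease-specific walk gamma_jk (== F2PRED
##            when K = 1).
##   Alt2   : h = {S, T, ST}; shared gamma_j in its own temporal
##            component with weight p_ikT.
##   Alt3a  : F2PRED with gamma_j scaled per disease: rho_k * gamma_j.
##   Alt3b  : F2PRED with a per-disease power: sign(g)|g|^rho_k.
## Components (per the model table):
##   M_S    = X_i' beta_kS + u_ik + v_i
##   M_T    = X_j' beta_kT + gamma_j                      (Alt2 only)
##   M_ST   = X_ij' beta_jkST [+ X_j' beta_kT + g_jk] + phi_ijk
## where the bracketed temporal terms sit inside M_ST for the
## two-component variants.

#' Construct a ModelSpec
#'
#' @param variant "F2PRED", "Alt1", "Alt2", "Alt3a" or "Alt3b".
#' @param nDiseases K in 1..3 (1 univariate, 2 bivariate, 3
#'   multivariate).  Alt3a/Alt3b require K >= 2.
#' @param C upper bound of the Unif(0, C) prior on every random-effect
#'   SD; a single number, or a named vector with a "default" entry and
#'   per-family overrides ("intercept", "beta", "u", "v", "gamma",
#'   "phi", "z", "mixA", "rho").
#' @param timeVaryingBetaST per-year spatio-temporal coefficient vectors
#'   (TRUE, default) or a single time-constant vector.
#' @param sharedTauZ Alt2 only: one CAR precision shared by the three
#'   mixture logit fields of a disease (default TRUE).
#' @param interceptOnly reduce the model to the intercept (sampler
#'   validation aid).
#' @param fixedSd named list of SDs to hold fixed instead of sampling,
#'   e.g. \code{list(intercept = 1)}.
#' @return a \code{\linkS4class{ModelSpec}}
#' @export
modelSpec <- function(variant = "Alt1", nDiseases = 1L, C = 10,
                      timeVaryingBetaST = TRUE, sharedTauZ = TRUE,
                      interceptOnly = FALSE, fixedSd = list()) {
  if (is.null(names(C))) C <- c(default = unname(C[1]))
  if (!"default" %in% names(C)) C <- c(C, default = 10)
  new("ModelSpec", variant = variant, nDiseases = as.integer(nDiseases),
      sdBound = C, timeVaryingBetaST = timeVaryingBetaST, sharedTauZ = sharedTauZ,
      interceptOnly = interceptOnly, fixedSd = fixedSd)
}

.getC <- function(spec, family) {
  if (family %in% names(spec@sdBound)) spec@sdBound[[family]] else spec@sdBound[["default"]]
}

.nMixComponents <- function(spec) if (spec@variant == "Alt2") 3L else 2L

## number of gamma columns carried in the state
.nGammaCols <- function(spec) {
  if (spec@variant == "Alt1" && spec@nDiseases > 1L) spec@nDiseases else 1L
}

.sdFamilies <- function(spec) {
  fam <- c("intercept", "beta", "u", "v", "gamma", "phi", "z", "mixA")
  if (spec@variant == "Alt3a") fam <- c(fam, "rho")
  fam
}

#' Two-component mixture weights
#'
#' \eqn{p_S = \mathrm{logit}^{-1}(z + a)}, \eqn{p_{ST} = 1 - p_S}: the
#' county-level weight construction of the two-component variants
#' (F2PRED, Alt1, Alt3a, Alt3b).
#'
#' @param z CAR-correlated logit component (vector).
#' @param a uncorrelated logit component (vector, recycled).
#' @return matrix with columns "S" and "ST"; rows sum to 1.
#' @export
mixtureWeightsTwo <- function(z, a) {
  p <- .logistic(z + a)
  cbind(S = p, ST = 1 - p)
}

#' Three-component mixture weights (Alt2)
#'
#' \eqn{q_h = \mathrm{logit}^{-1}(z_h + a_h)} and
#' \eqn{p_h = q_h / \sum_h q_h} for h in \{S, T, ST\}.
#'
#' @param z,a n x 3 matrices (or length-3 vectors) of logit components.
#' @return n x 3 matrix with columns "S", "T", "ST"; rows sum to 1.
#' @export
mixtureWeightsThree <- function(z, a) {
  if (is.vector(z)) z <- matrix(z, 1)
  if (is.vector(a)) a <- matrix(a, 1)
  stopifnot(ncol(z) == 3L, ncol(a) == 3L)
  q <- .logistic(z + a)
  s <- rowSums(q)
  if (any(s == 0)) .stopf("degenerate mixture: all logit components underflow")
  p <- q / s
  colnames(p) <- c("S", "T", "ST")
  p
}

#' Per-disease scaling of the shared temporal walk (Alt3)
#'
#' Alt3a scales the shared random walk by a disease-specific
#' coefficient, \eqn{\rho_k \gamma_j}.  Alt3b applies a disease-specific
#' power; since \eqn{\gamma_j} may be negative and \eqn{\rho_k} is not
#' an integer, the power is applied sign-preservingly:
#' \eqn{\mathrm{sign}(\gamma_j)\,|\gamma_j|^{\rho_k}}, with 0 mapped to
#' 0.  This keeps the transform monotone and reduces to the identity at
#' \eqn{\rho_k = 1}.
#'
#' @param variant "Alt3a" or "Alt3b".
#' @param gamma temporal random-effect value(s).
#' @param rho per-disease scaling parameter (Alt3b requires rho > 0).
#' @return scaled value(s).
#' @export
alt3Scale <- function(variant, gamma, rho) {
  switch(variant,
    Alt3a = rho * gamma,
    Alt3b = {
      if (any(rho <= 0)) .stopf("Alt3b requires rho > 0")
      sign(gamma) * abs(gamma)^rho
    },
    .stopf("alt3Scale is defined for Alt3a/Alt3b, not '%s'", variant))
}

## effective J x K matrix of temporal-walk values entering the predictor
.gammaEffective <- function(spec, state, J, K) {
  g <- state$gamma
  switch(spec@variant,
    F2PRED = matrix(g[, 1], J, K),
    Alt1 = if (ncol(g) == K) g else matrix(g[, 1], J, K),
    Alt2 = matrix(g[, 1], J, K),
    Alt3a = outer(g[, 1], state$rho),
    Alt3b = {
      out <- matrix(0, J, K)
      for (k in seq_len(K)) out[, k] <- alt3Scale("Alt3b", g[, 1], state$rho[k])
      out
    })
}

## mixture weights from the logit fields; returns list of I x K matrices
.mixtureWeights <- function(spec, state) {
  if (.nMixComponents(spec) == 2L) {
    p <- .logistic(state$mixZ[, , 1] + state$mixA[, , 1])
    p <- matrix(p, dim(state$mixZ)[1], dim(state$mixZ)[2])
    list(S = p, T = NULL, ST = 1 - p)
  } else {
    I <- dim(state$mixZ)[1]; K <- dim(state$mixZ)[2]
    q <- .logistic(state$mixZ + state$mixA)
    q1 <- matrix(q[, , 1], I, K); q2 <- matrix(q[, , 2], I, K)
    q3 <- matrix(q[, , 3], I, K)
    s <- q1 + q2 + q3
    list(S = q1 / s, T = q2 / s, ST = q3 / s)
  }
}

## full I x J x K array of log relative risks
.linearPredictor <- function(spec, state, cov, I, J, K) {
  lt <- array(0, c(I, J, K))
  if (spec@interceptOnly) {
    for (k in seq_len(K)) lt[, , k] <- state$alpha0[k]
    return(lt)
  }
  Ps <- ncol(cov@spatial); Pt <- ncol(cov@temporal)
  Pst <- dim(cov@spacetime)[3]
  covS <- if (Ps) cov@spatial %*% state$betaS else matrix(0, I, K)
  covT <- if (Pt) cov@temporal %*% state$betaT else matrix(0, J, K)
  MS <- covS + state$u + state$v    # I x K (v recycled down columns)
  p <- .mixtureWeights(spec, state)
  gmat <- .gammaEffective(spec, state, J, K)
  Jb <- dim(state$betaST)[2]
  for (k in seq_len(K)) {
    cst <- matrix(0, I, J)
    if (Pst) for (j in seq_len(J))
      cst[, j] <- matrix(cov@spacetime[, j, ], I, Pst) %*%
        state$betaST[, min(j, Jb), k]
    if (spec@variant == "Alt2") {
      MT <- covT[, k] + gmat[, k]                    # length J
      MST <- cst + state$phi[, , k]                  # I x J
      lt[, , k] <- state$alpha0[k] + p$S[, k] * MS[, k] +
        outer(p$T[, k], MT) + p$ST[, k] * MST
    } else {
      MST <- cst + state$phi[, , k] +
        matrix(covT[, k] + gmat[, k], I, J, byrow = TRUE)
      lt[, , k] <- state$alpha0[k] + p$S[, k] * MS[, k] + (1 - p$S[, k]) * MST
    }
  }
  lt
}

#' Log relative risk of one cell
#'
#' Evaluates \eqn{\log \theta_{ijk} = \alpha_{0k} + \sum_h p_{ikh}
#' M_{ijkh}} for the given variant at the given parameter state.
#'
#' @param spec a \code{ModelSpec}.
#' @param state a parameter state (see \code{\link{initializeState}}).
#' @param cov a \code{CovariateSet}.
#' @param i,j,k county, year and disease indices (1-based); omit all
#'   three to obtain the full I x J x K array.
#' @return numeric scalar (or array).
#' @export
logRelativeRisk <- function(spec, state, cov, i = NULL, j = NULL, k = NULL) {
  I <- nrow(state$u); J <- nrow(state$gamma); K <- spec@nDiseases
  lt <- .linearPredictor(spec, state, cov, I, J, K)
  if (is.null(i)) return(lt)
  if (i < 1 || i > I || j < 1 || j > J || k < 1 || k > K)
    .stopf("index (%d, %d, %d) out of range for a %d x %d x %d grid",
           i, j, k, I, J, K)
  lt[i, j, k]
}

#' Poisson log-likelihood with pointwise matrix
#'
#' \eqn{y_{ijk} \sim \mathrm{Pois}(e_{ijk}\theta_{ijk})}; returns the
#' total log-likelihood and the pointwise array retained for WAIC.
#'
#' @param frame an imputed \code{StudyFrame} with expected counts.
#' @param spec a \code{ModelSpec}.
#' @param state a parameter state.
#' @param cov a \code{CovariateSet}.
#' @return list(total, pointwise) with pointwise an I x J x K array.
#' @export
logLikelihood <- function(frame, spec, state, cov) {
  d <- dim(frame)
  if (!hasExpectedCounts(frame)) .stopf("expected counts not computed")
  lt <- .linearPredictor(spec, state, cov, d[1], d[2], d[3])
  mu <- frame@expected * exp(lt)
  if (any(!is.finite(mu))) {
    bad <- which(!is.finite(mu), arr.ind = TRUE)[1, ]
    .stopf("non-finite Poisson mean at (county=%s, year=%s, disease=%s)",
           frame@countyIds[bad[1]], frame@years[bad[2]],
           frame@diseaseIds[bad[3]])
  }
  pw <- stats::dpois(frame@counts, mu, log = TRUE)
  list(total = sum(pw), pointwise = pw)
}

## undirected edge matrix (each pair once) and component count of a graph
.graphEdges <- function(graph) {
  I <- length(graph@countyIds)
  from <- rep(seq_len(I), graph@nNeighbors)
  to <- unlist(graph@neighbors)
  keep <- from < to
  cbind(from[keep], to[keep])
}

.graphComponents <- function(graph) {
  I <- length(graph@countyIds)
  comp <- integer(I); c0 <- 0L
  for (s in seq_len(I)) {
    if (comp[s]) next
    c0 <- c0 + 1L
    queue <- s
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      if (comp[i]) next
      comp[i] <- c0
      queue <- c(queue, graph@neighbors[[i]][comp[graph@neighbors[[i]]] == 0L])
    }
  }
  c0
}

## intrinsic CAR log kernel: (rank/2) log tau - (tau/2) sum_{i~l} (x_i - x_l)^2
.icarLogKernel <- function(x, tau, edges, rank) {
  rank / 2 * log(tau) - tau / 2 * sum((x[edges[, 1]] - x[edges[, 2]])^2)
}

## RW1 log kernel over columns of a J x m matrix
.rw1LogKernel <- function(g, tau) {
  J <- nrow(g)
  sum((J - 1) / 2 * log(tau) - tau / 2 * colSums(diff(g)^2))
}

#' Joint log-prior of a parameter state
#'
#' Sums the log-densities of every effect under its prior: iid normal
#' terms (intercepts, fixed effects, u, phi, a-logits, Alt3a rho),
#' intrinsic CAR pairwise-difference kernels for v and the z fields,
#' RW1 kernels for gamma, Gamma(2, 1) for Alt3b rho, and the flat
#' Unif(0, C) density for every sampled SD.  Outside the support
#' (an SD outside (0, C), or Alt3b rho <= 0) the value is -Inf.
#'
#' @param spec a \code{ModelSpec}.
#' @param state a parameter state.
#' @param graph an \code{AdjacencyGraph} (ignored for intercept-only).
#' @return scalar log-prior (improper kernels up to constants).
#' @export
logPrior <- function(spec, state, graph = NULL) {
  sg <- state$sigma
  ## support checks first
  for (fam in names(sg)) {
    if (fam %in% names(spec@fixedSd)) next
    Cf <- .getC(spec, fam)
    if (any(sg[[fam]] <= 0 | sg[[fam]] >= Cf)) return(-Inf)
  }
  lp <- 0
  ## flat Unif(0,C) densities of the sampled SDs
  for (fam in names(sg))
    if (!fam %in% names(spec@fixedSd))
      lp <- lp - length(sg[[fam]]) * log(.getC(spec, fam))
  lp <- lp + sum(stats::dnorm(state$alpha0, 0, sg$intercept, log = TRUE))
  if (spec@interceptOnly) return(lp)
  K <- spec@nDiseases
  lp <- lp + sum(stats::dnorm(c(state$betaS, state$betaT, state$betaST),
                              0, sg$beta, log = TRUE))
  for (k in seq_len(K)) {
    lp <- lp + sum(stats::dnorm(state$u[, k], 0, sg$u[k], log = TRUE))
    lp <- lp + sum(stats::dnorm(state$phi[, , k], 0, sg$phi[k], log = TRUE))
    lp <- lp + sum(stats::dnorm(state$mixA[, k, ], 0, sg$mixA[k], log = TRUE))
  }
  edges <- .graphEdges(graph)
  rank <- length(graph@countyIds) - .graphComponents(graph)
  lp <- lp + .icarLogKernel(state$v, 1 / sg$v^2, edges, rank)
  for (k in seq_len(K)) for (h in seq_len(dim(state$mixZ)[3]))
    lp <- lp + .icarLogKernel(state$mixZ[, k, h], 1 / sg$z[k]^2, edges, rank)
  lp <- lp + .rw1LogKernel(state$gamma, 1 / sg$gamma^2)
  if (spec@variant == "Alt3a")
    lp <- lp + sum(stats::dnorm(state$rho, 0, sg$rho, log = TRUE))
  if (spec@variant == "Alt3b") {
    if (any(state$rho <= 0)) return(-Inf)
    lp <- lp + sum(stats::dgamma(state$rho, shape = 2, rate = 1, log = TRUE))
  }
  lp
}
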