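#' @import methods
NULL

#' StudyFrame: a complete county x year x disease count panel
#'
#' Holds observed (possibly threshold-coded) incidence counts
#' \eqn{y_{ijk}}, populations at risk \eqn{n_{ij}}, and, once computed,
#' expected counts \eqn{e_{ijk}} on a complete I x J x K grid.  Cells
#' whose stored count is a censoring code rather than a true count are
#' marked in the \code{coded} mask so downstream code can never silently
#' treat a code as an observation.
#'
#' @slot countyIds character vector of I county labels.
#' @slot years integer vector of J consecutive calendar years.
#' @slot diseaseIds character vector of K disease labels (K in 1..3).
#' @slot counts I x J x K numeric array of non-negative integers
#'   (true counts or censoring codes).
#' @slot populations I x J matrix of positive populations at risk.
#' @slot expected I x J x K numeric array of expected counts; all-NA
#'   until computed via \code{\link{addExpectedCounts}}.
#' @slot coded I x J x K logical array marking threshold-coded cells.
#' @slot imputed logical flag: TRUE once coded cells have been replaced
#'   by truncated-Poisson draws.
#' @seealso \code{\link{readCounts}}, \code{\link{imputeThresholded}}
#' @export
setClass("StudyFrame",
  representation(
    countyIds = "character",
    years = "integer",
    diseaseIds = "character",
    counts = "array",
    populations = "matrix",
    expected = "array",
    coded = "array",
    imputed = "logical"
  )
)

setValidity("StudyFrame", function(object) {
  I <- length(object@countyIds); J <- length(object@years)
  K <- length(object@diseaseIds)
  msg <- character(0)
  if (I < 1L || J < 1L || K < 1L) msg <- c(msg, "empty index set")
  if (K > 3L) msg <- c(msg, "at most 3 diseases are supported")
  if (J > 1L && any(diff(object@years) != 1L))
    msg <- c(msg, "years must be consecutive")
  if (!identical(dim(object@counts), c(I, J, K)))
    msg <- c(msg, "counts must be an I x J x K array")
  if (!identical(dim(object@coded), c(I, J, K)))
    msg <- c(msg, "coded mask must be an I x J x K array")
  if (!identical(dim(object@expected), c(I, J, K)))
    msg <- c(msg, "expected must be an I x J x K array (all NA allowed)")
  if (!identical(dim(object@populations), c(I, J)))
    msg <- c(msg, "populations must be an I x J matrix")
  if (anyNA(object@counts) || any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative and complete")
  if (any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be integer-valued")
  if (anyNA(object@populations) || any(object@populations <= 0))
    msg <- c(msg, "populations must be strictly positive")
  if (length(object@imputed) != 1L) msg <- c(msg, "imputed must be scalar")
  if (length(msg)) msg else TRUE
})

#' AdjacencyGraph: symmetric county neighbor structure
#'
#' Drives the intrinsic CAR priors on the correlated spatial effect
#' \eqn{v_i} and the CAR mixture-logit fields \eqn{z}.  Each county must
#' have at least one neighbor; the relation is symmetric with no
#' self-edges.
#'
#' @slot countyIds character vector of I county labels.
#' @slot neighbors list of I integer vectors; \code{neighbors[[i]]} are
#'   the indices of the neighbors of county i.
#' @slot nNeighbors integer vector, \eqn{n_i} = number of neighbors.
#' @seealso \code{\link{readAdjacency}}, \code{\link{makeLattice}}
#' @export
setClass("AdjacencyGraph",
  representation(
    countyIds = "character",
    neighbors = "list",
    nNeighbors = "integer"
  )
)

setValidity("AdjacencyGraph", function(object) {
  I <- length(object@countyIds)
  msg <- character(0)
  if (length(object@neighbors) != I || length(object@nNeighbors) != I)
    msg <- c(msg, "neighbors and nNeighbors must have one entry per county")
  for (i in seq_len(I)) {
    nb <- object@neighbors[[i]]
    if (length(nb) == 0L) {
      msg <- c(msg, sprintf("county '%s' is isolated", object@countyIds[i]))
      next
    }
    if (any(nb == i))
      msg <- c(msg, sprintf("self-edge at county '%s'", object@countyIds[i]))
    if (any(nb < 1L | nb > I)) msg <- c(msg, "neighbor index out of range")
    if (!all(vapply(nb, function(l) i %in% object@neighbors[[l]], logical(1))))
      msg <- c(msg, sprintf("asymmetric adjacency at county '%s'",
                            object@countyIds[i]))
    if (object@nNeighbors[i] != length(nb))
      msg <- c(msg, "nNeighbors inconsistent with neighbor lists")
  }
  if (length(msg)) msg[1:min(3, length(msg))] else TRUE
})

#' CovariateSet: spatial, temporal and spatio-temporal predictors
#'
#' @slot spatial I x P_S matrix (one row per county).
#' @slot temporal J x P_T matrix (one row per year).
#' @slot spacetime I x J x P_ST array.
#' @slot standardized logical; TRUE after \code{\link{standardizeCovariates}}.
#' @slot centers,scales named lists storing the standardization
#'   constants per block, for de-standardization.
#' @export
setClass("CovariateSet",
  representation(
    spatial = "matrix",
    temporal = "matrix",
    spacetime = "array",
    standardized = "logical",
    centers = "list",
    scales = "list"
  )
)

setValidity("CovariateSet", function(object) {
  msg <- character(0)
  if (length(dim(object@spacetime)) != 3L)
    msg <- c(msg, "spacetime must be a 3-d array (I x J x P_ST)")
  if (anyNA(object@spatial) || anyNA(object@temporal) || anyNA(object@spacetime))
    msg <- c(msg, "covariates must not contain NA")
  if (length(msg)) msg else TRUE
})

#' ThresholdScheme: the data provider's small-count recoding rule
#'
#' Each row (code, lower, upper) states that a true count in
#' [lower, upper] is reported as \code{code}.  The default scheme codes
#' counts 1-4 as 5 and counts 5-9 as 10; zeros are reported as true
#' zeros and are never coded.
#'
#' @slot codes integer censoring codes.
#' @slot lower,upper integer interval bounds (inclusive).
#' @export
setClass("ThresholdScheme",
  representation(codes = "integer", lower = "integer", upper = "integer")
)

setValidity("ThresholdScheme", function(object) {
  msg <- character(0)
  n <- length(object@codes)
  if (length(object@lower) != n || length(object@upper) != n)
    msg <- c(msg, "codes, lower, upper must have equal length")
  if (any(object@lower > object@upper)) msg <- c(msg, "lower must be <= upper")
  if (anyDuplicated(object@codes)) msg <- c(msg, "codes must be distinct")
  if (n > 1L) {
    o <- order(object@lower)
    if (any(object@lower[o][-1L] <= object@upper[o][-n]))
      msg <- c(msg, "intervals must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' ModelSpec: which mixture variant, how many diseases, which priors
#'
#' Encodes one row family of the model table: the variant name, the
#' number of diseases K (1 = univariate, 2 = bivariate, 3 =
#' multivariate), the upper bound C of the Unif(0, C) priors on all
#' random-effect standard deviations, and structural switches.
#'
#' @slot variant one of "F2PRED", "Alt1", "Alt2", "Alt3a", "Alt3b".
#' @slot nDiseases integer K in 1..3; Alt3a/Alt3b require K >= 2.
#' @slot sdBound named numeric vector of Unif(0, C) upper bounds; must contain
#'   a "default" entry, other entries override per effect family.
#' @slot timeVaryingBetaST logical; TRUE gives each study year its own
#'   spatio-temporal coefficient vector \eqn{\beta_{jk}^{ST}}.
#' @slot sharedTauZ logical; for Alt2, whether the three CAR mixture
#'   logit fields of a disease share one precision.
#' @slot interceptOnly logical; reduces the model to the intercept
#'   alone (used for sampler validation).
#' @slot fixedSd named list of standard deviations held fixed (not
#'   sampled), e.g. \code{list(intercept = 1)}.
#' @export
setClass("ModelSpec",
  representation(
    variant = "character",
    nDiseases = "integer",
    sdBound = "numeric",
    timeVaryingBetaST = "logical",
    sharedTauZ = "logical",
    interceptOnly = "logical",
    fixedSd = "list"
  )
)

setValidity("ModelSpec", function(object) {
  msg <- character(0)
  if (!object@variant %in% c("F2PRED", "Alt1", "Alt2", "Alt3a", "Alt3b"))
    msg <- c(msg, sprintf("unknown variant '%s'; valid: %s", object@variant,
                          "F2PRED, Alt1, Alt2, Alt3a, Alt3b"))
  if (!(object@nDiseases %in% 1:3)) msg <- c(msg, "nDiseases must be 1, 2 or 3")
  if (object@variant %in% c("Alt3a", "Alt3b") && object@nDiseases < 2L)
    msg <- c(msg, "Alt3a/Alt3b are only defined for bivariate/multivariate fits")
  if (!"default" %in% names(object@sdBound)) msg <- c(msg, "C must have a 'default' entry")
  if (any(object@sdBound <= 0)) msg <- c(msg, "C bounds must be positive")
  if (length(msg)) msg else TRUE
})

#' McmcConfig: sampler run configuration
#'
#' Defaults mirror the published analysis: 2 chains, 45,000 burn-in
#' iterations and 5,000 retained samples.  Tests and examples use much
#' shorter, scaled runs; the published run length is a default, not a
#' correctness requirement.
#'
#' @slot nChains,nBurnin,nSamples,thin integers.
#' @slot seed master integer seed; per-chain seeds are derived from it.
#' @slot adaptEvery adaptation batch size (iterations) during burn-in.
#' @slot targetAccept target Metropolis acceptance rate (0.44).
#' @slot recenter logical; apply sum-to-zero recentering of v, gamma and
#'   z fields each sweep (WinBUGS car.normal convention).
#' @slot randomizeOrder logical; permute the block update order each
#'   sweep (random-scan mode, used for order-invariance checks).
#' @slot priorOnly logical; switch the likelihood off and sample the
#'   prior (used for sampler validation).
#' @slot verbose logical.
#' @export
setClass("McmcConfig",
  representation(
    nChains = "integer", nBurnin = "integer", nSamples = "integer",
    thin = "integer", seed = "integer", adaptEvery = "integer",
    targetAccept = "numeric", recenter = "logical",
    randomizeOrder = "logical", priorOnly = "logical", verbose = "logical"
  )
)

setValidity("McmcConfig", function(object) {
  msg <- character(0)
  if (object@nBurnin < 0L) msg <- c(msg, "nBurnin must be >= 0")
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be > 0")
  if (object@nChains < 1L) msg <- c(msg, "nChains must be >= 1")
  if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
  if (object@targetAccept <= 0 || object@targetAccept >= 1)
    msg <- c(msg, "targetAccept must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' PosteriorSamples: MCMC draws plus pointwise quantities
#'
#' Retained posterior draws of every parameter (flattened, with labelled
#' columns), the pointwise log-likelihood matrix used for WAIC, and
#' posterior-predictive count draws used for MSPE.  Shared effects
#' (v, and gamma where shared) are stored once, not per disease.
#'
#' @slot draws nDraws x nPar numeric matrix with labelled columns.
#' @slot chain integer chain id per draw row.
#' @slot pointwiseLogLik nDraws x nCells matrix.
#' @slot yRep nDraws x nCells posterior-predictive counts.
#' @slot cellIndex data.frame mapping pointwise columns to
#'   (county, year, disease).
#' @slot acceptance named list of final acceptance rates per block.
#' @slot proposalScales named list of final proposal scales.
#' @slot spec the \code{\linkS4class{ModelSpec}} that was fit.
#' @slot config the \code{\linkS4class{McmcConfig}} used.
#' @export
setClass("PosteriorSamples",
  representation(
    draws = "matrix",
    chain = "integer",
    pointwiseLogLik = "matrix",
    yRep = "matrix",
    cellIndex = "data.frame",
    acceptance = "list",
    proposalScales = "list",
    spec = "ModelSpec",
    config = "McmcConfig"
  )
)

setValidity("PosteriorSamples", function(object) {
  msg <- character(0)
  if (nrow(object@draws) != length(object@chain))
    msg <- c(msg, "one chain id per draw row required")
  if (nrow(object@pointwiseLogLik) && nrow(object@pointwiseLogLik) != nrow(object@draws))
    msg <- c(msg, "pointwiseLogLik rows must match draws")
  if (length(msg)) msg else TRUE
})
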