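#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("countyIds", "StudyFrame", function(x) x@countyIds)
#' @rdname accessors
#' @export
setMethod("countyIds", "AdjacencyGraph", function(x) x@countyIds)
#' @rdname accessors
#' @export
setMethod("studyYears", "StudyFrame", function(x) x@years)
#' @rdname accessors
#' @export
setMethod("diseaseIds", "StudyFrame", function(x) x@diseaseIds)
#' @rdname accessors
#' @export
setMethod("counts", "StudyFrame", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("populations", "StudyFrame", function(x) x@populations)
#' @rdname accessors
#' @export
setMethod("expectedCounts", "StudyFrame", function(x) x@expected)
#' @rdname accessors
#' @export
setMethod("codedMask", "StudyFrame", function(x) x@coded)
#' @rdname accessors
#' @export
setMethod("isImputed", "StudyFrame", function(x) x@imputed)

#' @rdname accessors
#' @export
setMethod("neighbors", "AdjacencyGraph", function(x) x@neighbors)
#' @rdname accessors
#' @export
setMethod("nNeighbors", "AdjacencyGraph", function(x) x@nNeighbors)

#' @rdname accessors
#' @export
setMethod("isStandardized", "CovariateSet", function(x) x@standardized)

#' @rdname accessors
#' @export
setMethod("drawMatrix", "PosteriorSamples", function(x) x@draws)
#' @rdname accessors
#' @export
setMethod("chainIds", "PosteriorSamples", function(x) x@chain)
#' @rdname accessors
#' @export
setMethod("pointwiseLogLik", "PosteriorSamples", function(x) x@pointwiseLogLik)
#' @rdname accessors
#' @export
setMethod("yRep", "PosteriorSamples", function(x) x@yRep)
#' @rdname accessors
#' @export
setMethod("cellIndex", "PosteriorSamples", function(x) x@cellIndex)
#' @rdname accessors
#' @export
setMethod("modelVariant", "ModelSpec", function(x) x@variant)
#' @rdname accessors
#' @export
setMethod("modelVariant", "PosteriorSamples", function(x) x@spec@variant)

#' Dimensions of a StudyFrame
#'
#' @param x a \code{StudyFrame}
#' @return integer vector (I counties, J years, K diseases)
#' @export
setMethod("dim", "StudyFrame", function(x) {
  c(length(x@countyIds), length(x@years), length(x@diseaseIds))
})

#' Does a StudyFrame carry computed expected counts?
#' @param x a \code{StudyFrame}
#' @return logical
#' @export
hasExpectedCounts <- function(x) {
  stopifnot(is(x, "StudyFrame"))
  !anyNA(x@expected)
}

#' Extract posterior draws of one parameter family
#'
#' @param samples a \code{PosteriorSamples}
#' @param name parameter family name, e.g. "alpha0", "v", "gamma", "u",
#'   "phi", "mixZ", "mixA", "betaS", "sigma.v"
#' @return matrix of draws (nDraws x nElements) for the family
#' @export
paramDraws <- function(samples, name) {
  stopifnot(is(samples, "PosteriorSamples"))
  cols <- grep(paste0("^", gsub("\\.", "\\\\.", name), "(\\[|$)"),
               colnames(samples@draws))
  if (!length(cols)) .stopf("no parameter family '%s' in samples", name)
  samples@draws[, cols, drop = FALSE]
}

setMethod("show", "StudyFrame", function(object) {
  d <- dim(object)
  cat(sprintf("StudyFrame: %d counties x %d years (%d-%d) x %d disease(s)\n",
              d[1], d[2], min(object@years), max(object@years), d[3]))
  cat(sprintf("  diseases: %s\n", paste(object@diseaseIds, collapse = ", ")))
  cat(sprintf("  coded cells: %d; imputed: %s; expected counts: %s\n",
              sum(object@coded), object@imputed,
              if (hasExpectedCounts(object)) "computed" else "not computed"))
})

setMethod("show", "AdjacencyGraph", function(object) {
  cat(sprintf("AdjacencyGraph: %d counties, %d edges, neighbors per county %d-%d\n",
              length(object@countyIds), sum(object@nNeighbors) / 2L,
              min(object@nNeighbors), max(object@nNeighbors)))
})

setMethod("show", "CovariateSet", function(object) {
  cat(sprintf("CovariateSet: %d spatial, %d temporal, %d spatio-temporal column(s); standardized: %s\n",
              ncol(object@spatial), ncol(object@temporal),
              dim(object@spacetime)[3], object@standardized))
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s, K = %d (%s)%s\n", object@variant,
              object@nDiseases,
              c("univariate", "bivariate", "multivariate")[object@nDiseases],
              if (object@interceptOnly) " [intercept-only]" else ""))
  cat(sprintf("  Unif(0,C) SD bound: C = %s; time-varying beta_ST: %s\n",
              object@sdBound[["default"]], object@timeVaryingBetaST))
})

setMethod("show", "ThresholdScheme", function(object) {
  cat("ThresholdScheme:\n")
  for (r in seq_along(object@codes))
    cat(sprintf("  count in [%d, %d] reported as %d\n",
                object@lower[r], object@upper[r], object@codes[r]))
})

setMethod("show", "McmcConfig", function(object) {
  cat(sprintf("McmcConfig: %d chain(s), burn-in %d, samples %d, thin %d, seed %d\n",
              object@nChains, object@nBurnin, object@nSamples,
              object@thin, object@seed))
})

setMethod("show", "PosteriorSamples", function(object) {
  cat(sprintf("PosteriorSamples: %s fit, %d draws (%d chain(s)) of %d parameters\n",
              object@spec@variant, nrow(object@draws),
              length(unique(object@chain)), ncol(object@draws)))
  cat(sprintf("  pointwise log-lik over %d cells; posterior-predictive draws stored\n",
              ncol(object@pointwiseLogLik)))
})
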