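## preprocess module: overall disease rates, expected counts, truncated
## Poisson imputation of threshold-coded counts, and SIRs.
##
## The pipeline is two-pass: expected counts computed from the coded
## values parameterize the truncated-Poisson imputation, and the
## expected counts actually used in model fitting are recomputed from
## the imputed counts.

#' Construct a ThresholdScheme
#'
#' @param codes integer censoring codes.
#' @param lower,upper inclusive interval bounds per code.
#' @return a \code{\linkS4class{ThresholdScheme}}
#' @export
thresholdScheme <- function(codes, lower, upper) {
  new("ThresholdScheme", codes = as.integer(codes), lower = as.integer(lower),
      upper = as.integer(upper))
}

#' The default small-count recoding rule
#'
#' Counts 1-4 are reported as 5; counts 5-9 are reported as 10.  Zeros
#' are true zeros and counts of 10 or more are reported exactly.
#'
#' @return a \code{\linkS4class{ThresholdScheme}}
#' @export
defaultThresholdScheme <- function() {
  thresholdScheme(codes = c(5L, 10L), lower = c(1L, 5L), upper = c(4L, 9L))
}

#' Read / write a ThresholdScheme as JSON
#'
#' @param path JSON file path.
#' @return the scheme (read) or the path, invisibly (write).
#' @export
readThresholdScheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  thresholdScheme(x$code, x$lower, x$upper)
}

#' @rdname readThresholdScheme
#' @param scheme a \code{ThresholdScheme}.
#' @export
writeThresholdScheme <- function(scheme, path) {
  jsonlite::write_json(data.frame(code = scheme@codes, lower = scheme@lower,
                                  upper = scheme@upper),
                       path, auto_unbox = FALSE)
  invisible(path)
}

#' Overall rate of disease
#'
#' Total incidence over the whole study period divided by the total
#' population at risk (person-years), per disease.  At the imputation
#' stage the coded values are used as-is, matching the published
#' procedure.
#'
#' @param frame a \code{StudyFrame}.
#' @param disease disease label or index; NULL (default) returns all.
#' @return named numeric vector of rates per person per year.
#' @export
overallRate <- function(frame, disease = NULL) {
  stopifnot(is(frame, "StudyFrame"))
  totPop <- sum(frame@populations)
  if (totPop <= 0) .stopf("total population at risk is zero")
  kset <- if (is.null(disease)) seq_along(frame@diseaseIds)
          else .matchDisease(frame, disease)
  rates <- vapply(kset, function(k) sum(frame@counts[, , k]) / totPop,
                  numeric(1))
  stats::setNames(rates, frame@diseaseIds[kset])
}

.matchDisease <- function(frame, disease) {
  if (is.numeric(disease)) return(as.integer(disease))
  k <- match(as.character(disease), frame@diseaseIds)
  if (anyNA(k)) .stopf("unknown disease '%s'", disease[which(is.na(k))[1]])
  k
}

#' Attach expected counts e = rate * population
#'
#' \eqn{e_{ijk} = \mathrm{rate}_k \cdot n_{ij}}: the per-disease overall
#' rate times the county-year population at risk.
#'
#' @param frame a \code{StudyFrame}.
#' @param rates named numeric vector of per-disease rates; defaults to
#'   \code{overallRate(frame)}.
#' @return the frame with the expected slot filled.
#' @export
addExpectedCounts <- function(frame, rates = overallRate(frame)) {
  stopifnot(is(frame, "StudyFrame"))
  d <- dim(frame)
  if (length(rates) != d[3]) .stopf("need one rate per disease")
  if (any(rates < 0)) .stopf("rates must be non-negative")
  e <- array(NA_real_, d, dimnames = dimnames(frame@counts))
  for (k in seq_len(d[3])) e[, , k] <- rates[k] * frame@populations
  frame@expected <- e
  frame
}

#' Draw from a Poisson distribution truncated to [lower, upper]
#'
#' Exact inverse-CDF sampling on the finite support.  If the interval
#' carries essentially no Poisson mass (total probability < 1e-12) the
#' draw falls back to a uniform over the interval, with a warning.
#'
#' @param n number of draws.
#' @param lambda Poisson mean (scalar or length n).
#' @param lower,upper inclusive integer bounds.
#' @return integer vector of draws in [lower, upper].
#' @export
rtruncPois <- function(n, lambda, lower, upper) {
  support <- lower:upper
  lambda <- rep_len(lambda, n)
  out <- integer(n)
  u <- stats::runif(n)
  for (lam in unique(lambda)) {
    idx <- which(lambda == lam)
    pmf <- stats::dpois(support, lam)
    tot <- sum(pmf)
    if (tot < 1e-12) {
      .warnf("truncated support [%d, %d] has negligible Poisson mass at mean %.3g; using uniform draw",
             lower, upper, lam)
      pmf <- rep(1, length(support)); tot <- length(support)
    }
    cdf <- cumsum(pmf / tot)
    out[idx] <- support[findInterval(u[idx], cdf, left.open = TRUE) + 1L]
  }
  out
}

#' Impute threshold-coded counts
#'
#' Each coded cell is replaced by a draw from a Poisson distribution
#' with the cell's expected count as mean, truncated to the interval of
#' its censoring code.  True (uncoded) counts are left untouched.
#' Expected counts must already be present (computed from the coded
#' values); recompute them from the imputed counts afterwards with
#' \code{\link{recomputeExpected}} before model fitting.
#'
#' @param frame a \code{StudyFrame} with expected counts.
#' @param scheme a \code{ThresholdScheme}.
#' @param seed integer seed for reproducibility.
#' @return the frame with coded cells imputed and \code{isImputed} TRUE.
#' @export
imputeThresholded <- function(frame, scheme = defaultThresholdScheme(),
                              seed = 1L) {
  stopifnot(is(frame, "StudyFrame"), is(scheme, "ThresholdScheme"))
  if (!hasExpectedCounts(frame))
    .stopf("expected counts must be computed before imputation (addExpectedCounts)")
  set.seed(as.integer(seed))
  counts <- frame@counts
  for (r in seq_along(scheme@codes)) {
    idx <- which(frame@coded & counts == scheme@codes[r])
    if (!length(idx)) next
    counts[idx] <- rtruncPois(length(idx), frame@expected[idx],
                              scheme@lower[r], scheme@upper[r])
  }
  left <- which(frame@coded & !(frame@counts %in% scheme@codes))
  if (length(left))
    .stopf("coded cell with value %d matches no threshold code",
           frame@counts[left[1]])
  frame@counts <- counts
  frame@coded[] <- FALSE
  frame@imputed <- TRUE
  frame
}

#' Recompute expected counts from imputed counts
#'
#' The expected counts used in model fitting are computed from the
#' imputed data: per-disease overall rate times population.  Per
#' disease, the recomputed expected counts sum exactly to the observed
#' counts.
#'
#' @param frame an imputed \code{StudyFrame}.
#' @return the frame with refreshed expected counts.
#' @export
recomputeExpected <- function(frame) {
  stopifnot(is(frame, "StudyFrame"))
  addExpectedCounts(frame, overallRate(frame))
}

#' Standardized incidence ratios
#'
#' \eqn{\mathrm{SIR}_{ijk} = y_{ijk} / e_{ijk}}; a value of 1 means the
#' observed incidence equals the expected count.
#'
#' @param frame a \code{StudyFrame} with positive expected counts.
#' @return I x J x K numeric array of SIRs.
#' @export
computeSIR <- function(frame) {
  stopifnot(is(frame, "StudyFrame"))
  if (!hasExpectedCounts(frame)) .stopf("expected counts not computed")
  if (any(frame@expected <= 0))
    .stopf("expected count is zero; SIR undefined")
  frame@counts / frame@expected
}
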