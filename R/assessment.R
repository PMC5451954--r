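## assessment module: WAIC (with the variance-form effective-parameter
## penalty), MSPE from posterior-predictive draws, decomposition by
## disease and year window, and the total-random-component summary used
## to interpret fitted mixtures.

#' Watanabe-Akaike information criterion
#'
#' \eqn{\mathrm{lppd} = \sum_c \log(\frac{1}{S}\sum_s e^{\ell_{sc}})}
#' (computed with log-sum-exp stabilization),
#' \eqn{p_\mathrm{WAIC} = \sum_c \mathrm{Var}_s(\ell_{sc})} and
#' \eqn{\mathrm{WAIC} = -2(\mathrm{lppd} - p_\mathrm{WAIC})}.  The
#' effective-parameter count \eqn{p_\mathrm{WAIC}} is what the fit
#' tables report as "pD".
#'
#' @param ll draws x cells pointwise log-likelihood matrix, or a
#'   \code{PosteriorSamples}.
#' @param mask optional logical/integer cell subset.
#' @return list(waic, pWaic, lppd, pointwiseElpd)
#' @export
waic <- function(ll, mask = NULL) {
  if (is(ll, "PosteriorSamples")) ll <- pointwiseLogLik(ll)
  if (!is.null(mask)) ll <- ll[, mask, drop = FALSE]
  if (nrow(ll) < 2L) .stopf("WAIC requires at least 2 draws")
  if (ncol(ll) < 1L) .stopf("cell subset is empty")
  S <- nrow(ll)
  lppdC <- apply(ll, 2, logSumExp) - log(S)
  pC <- apply(ll, 2, stats::var)
  list(waic = -2 * (sum(lppdC) - sum(pC)), pWaic = sum(pC),
       lppd = sum(lppdC), pointwiseElpd = lppdC - pC)
}

#' Compare two fits by WAIC with a difference standard error
#'
#' Both fits must share the same cells (same frame).  The SE of the
#' WAIC difference is the usual pointwise one:
#' \eqn{2\sqrt{n \, \mathrm{Var}_c(\Delta \mathrm{elpd}_c)}}.
#'
#' @param llA,llB pointwise log-likelihood matrices (or
#'   \code{PosteriorSamples}).
#' @param mask optional cell subset applied to both.
#' @return list(waicA, waicB, diff = waicA - waicB, se)
#' @export
waicCompare <- function(llA, llB, mask = NULL) {
  wA <- waic(llA, mask); wB <- waic(llB, mask)
  dElpd <- wA$pointwiseElpd - wB$pointwiseElpd
  n <- length(dElpd)
  list(waicA = wA$waic, waicB = wB$waic, diff = wA$waic - wB$waic,
       se = 2 * sqrt(n * stats::var(dElpd)))
}

#' Mean squared predictive error
#'
#' Mean over posterior-predictive draws and selected cells of
#' \eqn{(y^{rep} - y)^2}.
#'
#' @param yrep draws x cells posterior-predictive count matrix, or a
#'   \code{PosteriorSamples}.
#' @param y observed counts per cell (vector aligned with columns).
#' @param mask optional cell subset.
#' @param plugin if TRUE, use the plug-in form: squared error of the
#'   posterior-mean prediction instead of averaging over draws.
#' @return scalar MSPE.
#' @export
mspe <- function(yrep, y, mask = NULL, plugin = FALSE) {
  if (is(yrep, "PosteriorSamples")) yrep <- yRep(yrep)
  if (!is.null(mask)) {
    yrep <- yrep[, mask, drop = FALSE]
    y <- y[mask]
  }
  if (ncol(yrep) < 1L) .stopf("cell subset is empty")
  if (length(y) != ncol(yrep)) .stopf("y and yrep shapes do not align")
  if (plugin) mean((colMeans(yrep) - y)^2)
  else mean(sweep(yrep, 2, y)^2)
}

#' Deviance information criterion (non-default alternative)
#'
#' Computed from the pointwise log-likelihood matrix using the
#' variance-of-deviance effective-parameter approximation:
#' \eqn{p_D = \mathrm{Var}_s(D_s)/2} with \eqn{D_s = -2\sum_c \ell_{sc}},
#' \eqn{\mathrm{DIC} = \bar D + p_D}.  WAIC is the package's headline
#' criterion; DIC is provided for comparison only.
#'
#' @param ll draws x cells pointwise log-likelihood matrix, or a
#'   \code{PosteriorSamples}.
#' @param mask optional cell subset.
#' @return list(dic, pD, meanDeviance)
#' @export
dic <- function(ll, mask = NULL) {
  if (is(ll, "PosteriorSamples")) ll <- pointwiseLogLik(ll)
  if (!is.null(mask)) ll <- ll[, mask, drop = FALSE]
  if (nrow(ll) < 2L) .stopf("DIC requires at least 2 draws")
  if (ncol(ll) < 1L) .stopf("cell subset is empty")
  D <- -2 * rowSums(ll)
  pD <- stats::var(D) / 2
  list(dic = mean(D) + pD, pD = pD, meanDeviance = mean(D))
}

#' Goodness-of-fit table by disease and year window
#'
#' Evaluates WAIC, pWAIC ("pD") and MSPE on every disease x window
#' combination plus the all-disease rows, mirroring the published
#' table's layout (full period and sub-windows).
#'
#' @param samples a \code{PosteriorSamples}.
#' @param frame the fitted \code{StudyFrame}.
#' @param windows named list of length-2 year ranges (inclusive);
#'   default is the full study period only.
#' @param byDisease include per-disease rows (default TRUE).
#' @return data.frame(measure, disease, window, value)
#' @export
fitTable <- function(samples, frame, windows = NULL, byDisease = TRUE) {
  stopifnot(is(samples, "PosteriorSamples"), is(frame, "StudyFrame"))
  yrs <- frame@years
  if (is.null(windows))
    windows <- list(full = range(yrs))
  for (w in names(windows)) {
    rg <- windows[[w]]
    if (rg[1] > rg[2] || rg[1] < min(yrs) || rg[2] > max(yrs))
      .stopf("window '%s' [%d, %d] lies outside the study years %d-%d",
             w, rg[1], rg[2], min(yrs), max(yrs))
  }
  idx <- samples@cellIndex
  yObs <- as.vector(frame@counts)
  dis <- c(if (byDisease) frame@diseaseIds, "all")
  out <- list()
  for (dk in dis) for (w in names(windows)) {
    rg <- windows[[w]]
    mask <- idx$year >= rg[1] & idx$year <= rg[2] &
      (if (dk == "all") TRUE else idx$disease == dk)
    wa <- waic(samples@pointwiseLogLik, mask)
    ms <- mspe(samples@yRep, yObs, mask)
    out[[length(out) + 1L]] <- data.frame(
      measure = c("WAIC", "pD", "MSPE"), disease = dk, window = w,
      value = c(wa$waic, wa$pWaic, ms))
  }
  do.call(rbind, out)
}

#' Pretty-print a fit table
#'
#' @param tab output of \code{\link{fitTable}}.
#' @return the reshaped table (measure x window rows, disease columns),
#'   invisibly; printed as a side effect.
#' @export
printFitTable <- function(tab) {
  wide <- stats::reshape(tab, idvar = c("measure", "window"),
                         timevar = "disease", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide[, -(1:2)] <- round(wide[, -(1:2), drop = FALSE], 2)
  print(wide, row.names = FALSE)
  invisible(wide)
}

#' Posterior summary of the total random component
#'
#' For the three-component variants the per-cell total random component
#' is \eqn{p_{ikS}(u_{ik} + v_i) + p_{ikT}\gamma_j + p_{ikST}\phi_{ijk}}
#' -- the total of the confounding adjusted for in the fitted model.
#' For the two-component variants the analogous term is
#' \eqn{p_{ik}(u_{ik} + v_i) + (1 - p_{ik})(g_{jk} + \phi_{ijk})} with
#' \eqn{g} the (possibly scaled) temporal walk.  Mixture-weight
#' posterior means are reported alongside: a county with weights
#' (0.1, 0.5, 0.4) has 10\% of its risk variability explained by
#' spatial, 50\% by temporal and 40\% by spatio-temporal effects.
#'
#' @param samples a \code{PosteriorSamples}.
#' @param probs credible-interval probabilities (default 2.5\%/97.5\%).
#' @return list(summary = data.frame per cell with mean and CI,
#'   weights = data.frame of per-(county, disease) posterior mean
#'   weights and variance shares)
#' @export
randomComponentSummary <- function(samples, probs = c(0.025, 0.975)) {
  stopifnot(is(samples, "PosteriorSamples"))
  spec <- samples@spec
  idx <- samples@cellIndex
  I <- max(idx$i); J <- max(idx$j); K <- max(idx$k)
  H <- if (spec@variant == "Alt2") 3L else 1L
  X <- samples@draws
  S <- nrow(X)
  col <- function(nm) X[, nm, drop = TRUE]
  totals <- matrix(0, S, nrow(idx))
  pS <- pT <- pST <- array(0, c(S, I, K))
  uD <- array(0, c(S, I, K)); vD <- X[, sprintf("v[%d]", 1:I), drop = FALSE]
  for (k in seq_len(K)) {
    uD[, , k] <- X[, sprintf("u[%d,%d]", 1:I, k), drop = FALSE]
    if (H == 1L) {
      zz <- X[, sprintf("mixZ[%d,%d]", 1:I, k), drop = FALSE] +
        X[, sprintf("mixA[%d,%d]", 1:I, k), drop = FALSE]
      pS[, , k] <- .logistic(zz)
      pST[, , k] <- 1 - pS[, , k]
    } else {
      q <- array(0, c(S, I, 3))
      for (h in 1:3)
        q[, , h] <- .logistic(
          X[, sprintf("mixZ[%d,%d,%d]", 1:I, k, h), drop = FALSE] +
          X[, sprintf("mixA[%d,%d,%d]", 1:I, k, h), drop = FALSE])
      tot <- q[, , 1] + q[, , 2] + q[, , 3]
      pS[, , k] <- q[, , 1] / tot
      pT[, , k] <- q[, , 2] / tot
      pST[, , k] <- q[, , 3] / tot
    }
  }
  Kg <- if (spec@variant == "Alt1" && K > 1) K else 1L
  gam <- if (Kg == 1L) X[, sprintf("gamma[%d]", 1:J), drop = FALSE] else NULL
  rho <- if (spec@variant %in% c("Alt3a", "Alt3b"))
    X[, sprintf("rho[%d]", 1:K), drop = FALSE] else NULL
  for (c0 in seq_len(nrow(idx))) {
    i <- idx$i[c0]; j <- idx$j[c0]; k <- idx$k[c0]
    g <- if (Kg > 1L) col(sprintf("gamma[%d,%d]", j, k)) else gam[, j]
    if (!is.null(rho)) g <- alt3Scale(spec@variant, g, rho[, k])
    phi <- col(sprintf("phi[%d,%d,%d]", i, j, k))
    totals[, c0] <- if (H == 3L)
      pS[, i, k] * (uD[, i, k] + vD[, i]) + pT[, i, k] * g + pST[, i, k] * phi
    else
      pS[, i, k] * (uD[, i, k] + vD[, i]) + pST[, i, k] * (g + phi)
  }
  qs <- apply(totals, 2, stats::quantile, probs = probs)
  summary <- data.frame(idx[, c("county", "year", "disease")],
                        mean = colMeans(totals),
                        lower = qs[1, ], upper = qs[2, ])
  wgrid <- expand.grid(i = seq_len(I), k = seq_len(K))
  weights <- data.frame(
    county = unique(idx$county)[wgrid$i],
    disease = unique(idx$disease)[wgrid$k],
    pS = mapply(function(i, k) mean(pS[, i, k]), wgrid$i, wgrid$k),
    pT = if (H == 3L) mapply(function(i, k) mean(pT[, i, k]), wgrid$i, wgrid$k)
         else NA_real_,
    pST = mapply(function(i, k) mean(pST[, i, k]), wgrid$i, wgrid$k))
  weights$varianceShare <- if (H == 3L)
    sprintf("S %.0f%% / T %.0f%% / ST %.0f%%", 100 * weights$pS,
            100 * weights$pT, 100 * weights$pST)
  else
    sprintf("S %.0f%% / ST %.0f%%", 100 * weights$pS, 100 * weights$pST)
  list(summary = summary, weights = weights)
}
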