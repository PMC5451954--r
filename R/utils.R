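## Internal numerical helpers shared across modules.

#' Numerically stable log-sum-exp
#' @param x numeric vector
#' @return log(sum(exp(x)))
#' @keywords internal
#' @noRd
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## logistic with saturation safety; plogis is already safe but keep the
## name close to the model notation
.logistic <- function(x) stats::plogis(x)

## greedy graph coloring over an adjacency (list of integer neighbor
## vectors); returns integer color per node.  Used to batch single-site
## Metropolis updates of CAR / random-walk fields: nodes of one color are
## conditionally independent given the rest.
.greedyColoring <- function(neighbors) {
  n <- length(neighbors)
  colors <- integer(n)
  for (i in seq_len(n)) {
    used <- colors[neighbors[[i]]]
    c0 <- 1L
    while (c0 %in% used) c0 <- c0 + 1L
    colors[i] <- c0
  }
  colors
}

## neighbor structure of a 1-D path (for RW1 updates)
.pathNeighbors <- function(n) {
  lapply(seq_len(n), function(j) {
    nb <- c(j - 1L, j + 1L)
    nb[nb >= 1L & nb <= n]
  })
}

## derive a child seed from a master seed, kept below 2^31
.childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
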