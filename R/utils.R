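#' Logistic function
#'
#' Standard logistic (inverse logit), used throughout the item models.
#'
#' @param x Numeric vector.
#' @return Numeric vector of values in (0, 1).
#' @keywords internal
logistic <- function(x) 1 / (1 + exp(-x))

#' Numerically stable log-sum-exp
#' @param x Numeric vector of log-scale values.
#' @return Scalar log(sum(exp(x))).
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Gauss-Hermite nodes and weights
#'
#' Golub-Welsch computation of the n-point Gauss-Hermite rule for
#' integrals of the form `integral exp(-x^2) f(x) dx`.
#'
#' @param n Number of nodes (>= 1).
#' @return List with `nodes` and `weights`, each length `n`.
#' @export
#' @examples
#' gh <- gauss_hermite(7)
#' sum(gh$weights) # sqrt(pi)
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = (sqrt(pi) * e$vectors[1, ]^2)[ord])
}

## Gauss-Hermite rule rescaled for averaging against a Normal(mean, sd^2)
## density: E[f(X)] ~ sum(w * f(x)).
normal_quadrature <- function(n, mean = 0, sd = 1) {
  gh <- gauss_hermite(n)
  list(nodes = mean + sqrt(2) * sd * gh$nodes,
       weights = gh$weights / sqrt(pi))
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Derive reproducible child seeds from a master seed
#'
#' A single master seed deterministically spawns per-stage / per-replicate
#' seeds so that partial re-runs are reproducible. Seeds stay below 2^31.
#'
#' @param master Integer master seed.
#' @param n Number of child seeds.
#' @param stream Character tag distinguishing stages (e.g. "simulate").
#' @return Integer vector of `n` seeds.
#' @export
derive_seeds <- function(master, n, stream = "default") {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream))) %% 99991L
  s <- (as.double(master) * 48271 + h * 1009) %% 2147483647
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 48271 + 11) %% 2147483647
    out[i] <- s
  }
  as.integer(out %% 2147483587 + 1)
}

## internal: stop unless condition, with a contract-violation flavour
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg, class = "cogirt_contract_error")
  invisible(TRUE)
}
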