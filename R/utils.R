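#' Round half away from zero
#'
#' Display rounding used for efficacy tables: 0.005 rounds to 0.01, -0.005 to
#' -0.01. Base `round()` rounds half to even, which does not reproduce the
#' printed confidence bounds.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @param na.rm drop missing values.
#' @return geometric mean of `x`.
#' @export
geo_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  exp(mean(log(x)))
}

# log(sum(exp(x))) without overflow, by row of a matrix
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for \eqn{\int f(x) e^{-x^2} dx \approx \sum w_k f(x_k)},
#' computed by Golub-Welsch eigendecomposition of the Jacobi matrix.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights`, each length `n`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# deterministic integer sub-seed derived from a master seed and a stage tag,
# kept below 2^31
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (as.integer(seed) + 1009L * (h %% 9973L)) %% 2147483647L
}
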