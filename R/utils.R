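# Internal numerical helpers shared across modules.

#' @noRd
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Two-sided normal p-value from a z statistic
#' @noRd
z_to_p <- function(z) 2 * stats::pnorm(-abs(z))

#' Draw one multivariate normal vector with covariance R from its Cholesky root
#' @noRd
mvn_draw <- function(n_draws, chol_R) {
  p <- ncol(chol_R)
  matrix(stats::rnorm(n_draws * p), n_draws, p) %*% chol_R
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
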