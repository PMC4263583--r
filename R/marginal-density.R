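#' Marginal log-density of one equal-mean group
#'
#' Integrating the shared normal mean out of `n` conditionally independent
#' normal observations, `X_i | mu ~ N(mu, sigma_sq)` with
#' `mu ~ N(mu0, tau0_sq)`, gives an n-dimensional multivariate normal with
#' mean `(mu0, ..., mu0)` and compound-symmetric covariance
#' `sigma_sq * I + tau0_sq * J` (J the all-ones matrix). The determinant and
#' inverse have closed forms (rank-one update), so the log-density is
#' evaluated directly without forming the covariance matrix:
#' `det = sigma_sq^(n-1) * (sigma_sq + n * tau0_sq)`.
#'
#' @param x Numeric vector of expression values for one group.
#' @param mu0 Prior mean (FPKM units).
#' @param tau0_sq Prior variance of the group mean (FPKM^2), `>= 0`.
#' @param sigma_sq Observation variance (FPKM^2), `> 0`.
#' @return The log-density (scalar).
#' @examples
#' marginal_log_density(c(5), mu0 = 5, tau0_sq = 0, sigma_sq = 1)
#' # log(1/sqrt(2*pi))
#' @export
marginal_log_density <- function(x, mu0, tau0_sq, sigma_sq) {
  if (!all(is.finite(x)) || !is.finite(mu0) || !is.finite(tau0_sq) ||
      !is.finite(sigma_sq)) {
    stop("Non-finite input to marginal_log_density().", call. = FALSE)
  }
  if (sigma_sq <= 0) stop("`sigma_sq` must be > 0.", call. = FALSE)
  if (tau0_sq < 0) stop("`tau0_sq` must be >= 0.", call. = FALSE)
  n <- length(x)
  if (n < 1L) stop("`x` must have at least one value.", call. = FALSE)
  d <- x - mu0
  cs_log_density(sum(d^2), sum(d), n, sigma_sq, tau0_sq)
}

# Vectorised compound-symmetry log-density from sufficient statistics.
# ss = sum((x - mu0)^2), s = sum(x - mu0), n = group size; ss/s may be
# vectors (one element per transcript) with scalar or vector sigma_sq.
cs_log_density <- function(ss, s, n, sigma_sq, tau0_sq) {
  denom <- sigma_sq + n * tau0_sq
  quad <- ss / sigma_sq - tau0_sq * s^2 / (sigma_sq * denom)
  logdet <- (n - 1) * log(sigma_sq) + log(denom)
  -0.5 * (n * log(2 * pi) + logdet + quad)
}

#' Log-density of a whole transcript under one expression pattern
#'
#' A pattern partitions the samples into groups assumed to share one
#' underlying mean; groups are independent, so the pattern log-density is
#' the sum of the group marginals.
#'
#' @param x Numeric vector over all samples of one transcript.
#' @param pattern Integer group labels (contiguous `1..r`), one per sample.
#' @inheritParams marginal_log_density
#' @return The log-density (scalar).
#' @export
pattern_log_density <- function(x, pattern, mu0, tau0_sq, sigma_sq) {
  if (length(x) != length(pattern)) {
    stop("`x` and `pattern` must have the same length.", call. = FALSE)
  }
  groups <- split(x, pattern)
  sum(vapply(groups, marginal_log_density, numeric(1),
             mu0 = mu0, tau0_sq = tau0_sq, sigma_sq = sigma_sq))
}
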