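#' Asymptotic variance of a product of two estimators
#'
#' FPKM point estimates are products of two jointly asymptotically normal
#' maximum-likelihood estimates (a gene-level count and a transcript
#' fraction), which justifies modelling them as normal: if
#' `sqrt(n) (theta_hat - theta, eta_hat - eta)` converges to a bivariate
#' normal with marginal SDs `sigma1`, `sigma2` and correlation `rho`, then
#' `sqrt(n) (theta_hat * eta_hat - theta * eta)` converges to
#' `N(0, gamma^2)` with
#' `gamma^2 = eta^2 sigma1^2 + theta^2 sigma2^2 +
#'   2 eta theta sigma1 sigma2 rho`.
#'
#' @param theta,eta True parameter values.
#' @param sigma1,sigma2 Asymptotic standard deviations (>= 0).
#' @param rho Correlation of the two estimators, in `[-1, 1]`.
#' @return `gamma^2`, the asymptotic variance of the product (vectorised).
#' @examples
#' product_delta_variance(theta = 2, eta = 3, sigma1 = 1, sigma2 = 1) # 13
#' @export
product_delta_variance <- function(theta, eta, sigma1, sigma2, rho = 0) {
  if (any(sigma1 < 0) || any(sigma2 < 0)) {
    stop("`sigma1` and `sigma2` must be >= 0.", call. = FALSE)
  }
  if (any(abs(rho) > 1)) stop("`rho` must lie in [-1, 1].", call. = FALSE)
  eta^2 * sigma1^2 + theta^2 * sigma2^2 + 2 * eta * theta * sigma1 * sigma2 * rho
}
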