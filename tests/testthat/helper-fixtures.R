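# Shared fixtures and independent oracles.

# Expression table from a plain matrix.
make_expr_table <- function(values, conditions, ids = NULL) {
  ids <- ids %||% sprintf("t%04d", seq_len(nrow(values)))
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  names(conditions) <- colnames(values)
  tbl <- dplyr::bind_cols(tibble::tibble(transcript_id = ids),
                          tibble::as_tibble(values))
  as_expression_table(tbl, conditions)
}

# Independent oracle for the group marginal: adaptive 1-D quadrature of the
# defining integral  f0(x) = \int prod_i N(x_i; mu, sigma^2) N(mu; mu0,
# tau0^2) dmu, evaluated in the log domain around the integrand's peak.
quad_marginal_log_density <- function(x, mu0, tau0_sq, sigma_sq) {
  if (tau0_sq == 0) {
    return(sum(stats::dnorm(x, mu0, sqrt(sigma_sq), log = TRUE)))
  }
  g <- function(mu) {
    vapply(mu, function(m) {
      sum(stats::dnorm(x, m, sqrt(sigma_sq), log = TRUE)) +
        stats::dnorm(m, mu0, sqrt(tau0_sq), log = TRUE)
    }, numeric(1))
  }
  span <- range(c(x, mu0)) + c(-10, 10) * sqrt(tau0_sq + sigma_sq)
  opt <- stats::optimize(g, interval = span, maximum = TRUE)
  # integrate over a window that certainly holds all the mass: the
  # integrand's curvature is at least n/sigma^2 + 1/tau0^2
  s_post <- 1 / sqrt(length(x) / sigma_sq + 1 / tau0_sq)
  val <- stats::integrate(function(mu) exp(g(mu) - opt$objective),
                          opt$maximum - 15 * s_post,
                          opt$maximum + 15 * s_post, rel.tol = 1e-12)$value
  opt$objective + log(val)
}

# Two-condition study drawn from the hierarchical normal-normal model:
# shared prior N(mu0, tau0_sq) for condition means, observation sd sigma,
# a `p_de` fraction of transcripts with independent means per condition.
simulate_nn_study <- function(seed, n_transcripts = 5000L,
                              n_replicates = 5L, mu0 = 5, tau0_sq = 4,
                              sigma = 1, p_de = 0.1) {
  set.seed(seed)
  g <- n_transcripts
  de <- stats::rbinom(g, 1, p_de) == 1
  mu1 <- stats::rnorm(g, mu0, sqrt(tau0_sq))
  mu2 <- ifelse(de, stats::rnorm(g, mu0, sqrt(tau0_sq)), mu1)
  x <- cbind(
    matrix(stats::rnorm(g * n_replicates, mu1, sigma), g),
    matrix(stats::rnorm(g * n_replicates, mu2, sigma), g)
  )
  colnames(x) <- c(paste0("ctrl_", seq_len(n_replicates)),
                   paste0("treat_", seq_len(n_replicates)))
  cond <- stats::setNames(rep(c("ctrl", "treat"), each = n_replicates),
                          colnames(x))
  list(data = make_expr_table(x, cond), de = de, conditions = cond)
}

`%||%` <- rlang::`%||%`
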