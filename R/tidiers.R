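#' Broom-style tidiers for fitted empirical Bayes models
#'
#' `tidy()` returns the per-transcript posterior table in long form (one row
#' per transcript-pattern pair); `glance()` returns a one-row summary of the
#' fitted hyperparameters and the EM run.
#'
#' @param x An `eb_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @name eb_fit_tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname eb_fit_tidiers
#' @exportS3Method generics::tidy
tidy.eb_fit <- function(x, ...) {
  x$posteriors |>
    dplyr::select(-"call") |>
    tidyr::pivot_longer(-"transcript_id", names_to = "pattern",
                        values_to = "posterior")
}

#' @rdname eb_fit_tidiers
#' @exportS3Method generics::glance
glance.eb_fit <- function(x, ...) {
  tibble::tibble(
    mu0 = x$mu0, tau0_sq = x$tau0_sq,
    !!!stats::setNames(as.list(x$mix), paste0("p_", names(x$mix))),
    log_likelihood = utils::tail(x$log_likelihood_trace, 1L),
    n_iterations = x$n_iterations,
    converged = x$converged
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Diagnostic plot of the EM run
#'
#' Shows the marginal log-likelihood trace across EM iterations; a
#' well-behaved run is monotone non-decreasing and flattens at convergence.
#'
#' @param object An `eb_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.eb_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$log_likelihood_trace),
                       log_likelihood = object$log_likelihood_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$log_likelihood)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "EM iteration", y = "Marginal log-likelihood") +
    ggplot2::theme_minimal()
}
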