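#' Mean vs Fano-factor diagnostics of technical replicate counts
#'
#' For each gene, the Fano factor (sample variance / sample mean) across
#' technical replicates; under Poisson noise it sits near 1 for every mean,
#' while overdispersed sequencing noise makes it grow with the mean. An
#' ordinary least-squares line of Fano on mean is fitted over the genes
#' ranked by increasing mean, optionally restricted to the first
#' `first_k` genes so the low-mean bulk and the high-mean tail can be
#' examined separately.
#'
#' @param counts Data frame with a `transcript_id` column and one numeric
#'   column per technical replicate (>= 2), or a plain numeric matrix.
#' @param first_k Restrict the regression to the `first_k` genes with the
#'   smallest means (default: all).
#' @return Tibble of class `fano_tbl` (`transcript_id`, `mean`, `fano`),
#'   sorted by increasing mean; genes with zero mean are excluded and
#'   listed in the `excluded` attribute; the `fit` attribute holds the
#'   `lm` object, and `slope` / `intercept` its coefficients.
#' @export
fano_regression <- function(counts, first_k = NULL) {
  if (is.matrix(counts)) {
    ids <- rownames(counts) %||% sprintf("g%05d", seq_len(nrow(counts)))
    m <- counts
  } else {
    ids <- as.character(counts$transcript_id)
    m <- as.matrix(counts[setdiff(names(counts), "transcript_id")])
  }
  if (ncol(m) < 2L) {
    stop("Need >= 2 technical replicates per gene.", call. = FALSE)
  }
  mu <- rowMeans(m)
  v <- apply(m, 1L, stats::var)
  zero <- mu == 0
  if (all(zero)) stop("All gene means are zero.", call. = FALSE)
  out <- tibble::tibble(transcript_id = ids[!zero],
                        mean = unname(mu[!zero]),
                        fano = unname(v[!zero] / mu[!zero])) |>
    dplyr::arrange(.data$mean, .data$transcript_id)
  k <- min(first_k %||% nrow(out), nrow(out))
  fit <- stats::lm(fano ~ mean, data = out[seq_len(k), ])
  structure(out,
            excluded = ids[zero],
            fit = fit,
            slope = unname(stats::coef(fit)[["mean"]]),
            intercept = unname(stats::coef(fit)[["(Intercept)"]]),
            class = c("fano_tbl", class(out)))
}

#' @rdname fano_regression
#' @param object A `fano_tbl`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.fano_tbl <- function(object, ...) {
  fit <- attr(object, "fit", exact = TRUE)
  ggplot2::ggplot(object, ggplot2::aes(.data$mean, .data$fano)) +
    ggplot2::geom_point(shape = 1, alpha = 0.6) +
    ggplot2::geom_abline(slope = stats::coef(fit)[["mean"]],
                         intercept = stats::coef(fit)[["(Intercept)"]],
                         colour = "red") +
    ggplot2::labs(x = "Mean count", y = "Fano factor") +
    ggplot2::theme_minimal()
}
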