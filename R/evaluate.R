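#' Empirical ROC curve of a transcript ranking
#'
#' Standard empirical ROC over all thresholds of a per-transcript score
#' (e.g. the posterior probability of the DE pattern), with equal scores
#' grouped into a single step so tied transcripts move together. The curve
#' runs from (0, 0) to (1, 1); the area under it (AUC, trapezoid rule) is
#' attached as an attribute and returned by [roc_auc()].
#'
#' @param data Data frame with one row per transcript.
#' @param score Column of ranking scores (higher = more likely DE).
#' @param truth Column of true DE indicators (logical or 0/1).
#' @return Tibble of class `roc_curve_tbl` with columns `threshold`,
#'   `fpr`, `tpr`; attribute `auc`.
#' @export
roc_curve <- function(data, score, truth) {
  s <- dplyr::pull(data, {{ score }})
  l <- as.logical(dplyr::pull(data, {{ truth }}))
  if (length(unique(l)) < 2L) {
    stop("Both classes must be present to form an ROC curve.", call. = FALSE)
  }
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; l <- l[ord]
  # one step per distinct score value (ties grouped)
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_group]
  fp <- cumsum(!l)[last_of_group]
  curve <- tibble::tibble(
    threshold = c(Inf, s[last_of_group]),
    fpr = c(0, fp / sum(!l)),
    tpr = c(0, tp / sum(l))
  )
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  structure(curve, auc = auc,
            class = c("roc_curve_tbl", class(curve)))
}

#' @rdname roc_curve
#' @param x A `roc_curve_tbl`.
#' @export
roc_auc <- function(x) {
  auc <- attr(x, "auc", exact = TRUE)
  if (is.null(auc)) stop("Not a roc_curve() result.", call. = FALSE)
  auc
}

#' @rdname roc_curve
#' @param object A `roc_curve_tbl`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_curve_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.3f", roc_auc(object))) +
    ggplot2::theme_minimal()
}

#' True-discovery curve of a ranked transcript list
#'
#' For each cutoff `N`, how many of the top-`N` ranked transcripts are truly
#' differentially expressed. Pipes naturally from [rank_by_pattern()].
#'
#' @param data Data frame whose rows are transcripts in rank order (best
#'   first), with a `transcript_id` column.
#' @param truth Character vector of truly DE transcript ids.
#' @param max_n Largest cutoff (default: all ranked transcripts).
#' @return Tibble of class `tdc_tbl` with `n_selected`, `n_correct`.
#' @export
true_discovery_curve <- function(data, truth, max_n = nrow(data)) {
  if (max_n > nrow(data)) {
    stop("`max_n` exceeds the number of ranked transcripts.", call. = FALSE)
  }
  hits <- cumsum(data$transcript_id %in% truth)
  out <- tibble::tibble(n_selected = seq_len(max_n),
                        n_correct = as.integer(hits[seq_len(max_n)]))
  structure(out, class = c("tdc_tbl", class(out)))
}

#' @rdname true_discovery_curve
#' @param object A `tdc_tbl`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.tdc_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$n_selected, .data$n_correct)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Transcripts selected",
                  y = "Correctly identified transcripts") +
    ggplot2::theme_minimal()
}

#' Run the simulation study end to end
#'
#' Convenience wrapper used by the evaluation designs: simulate a
#' control/treatment study, fit the two-pattern empirical Bayes model
#' (posterior plug-in variances), score transcripts by the posterior DE
#' probability, and return the ROC AUC.
#'
#' @inheritParams simulate_expression
#' @param control An [eb_control()] for the fit.
#' @return The ROC AUC (scalar).
#' @export
simulation_auc <- function(n_transcripts = 1000L, de_fraction = 0.10,
                           mean_shift = 0, extra_variance = 0,
                           n_replicates = 10L, base_params = NULL,
                           seed = 1L, control = eb_control(tol = 1e-5)) {
  sim <- simulate_expression(n_transcripts, de_fraction, mean_shift,
                             extra_variance, n_replicates, base_params,
                             seed)
  cond <- expression_conditions(sim$data)
  fit <- eb_fit(sim$data, de_patterns(cond), control = control)
  scored <- dplyr::inner_join(rank_by_pattern(fit, "DE"), sim$truth,
                              by = "transcript_id")
  roc_auc(roc_curve(scored, "posterior", "de"))
}
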