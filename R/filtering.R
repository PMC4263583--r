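#' Drop extreme-abundance transcripts before model fitting
#'
#' Transcripts at the very bottom and very top of the abundance range
#' destabilise the mixture fit, so a small fraction of each tail is removed
#' before fitting: by default the 1% most lowly expressed and the 0.1% most
#' highly expressed, ranked by the grand mean across all samples. The number
#' removed per tail is `floor(fraction * G)` (conservative), ties broken by
#' transcript id.
#'
#' @param data Expression table.
#' @param low_fraction Fraction of lowest-expressed transcripts to drop.
#' @param high_fraction Fraction of highest-expressed transcripts to drop.
#' @return The filtered expression table; the `removed` attribute holds a
#'   tibble (`transcript_id`, `summary`, `tail`) of what was dropped.
#' @examples
#' # At G = 1000 with the defaults, 10 low + 1 high transcripts are removed.
#' @export
filter_extremes <- function(data, low_fraction = 0.01,
                            high_fraction = 0.001) {
  if (low_fraction < 0 || low_fraction >= 1 ||
      high_fraction < 0 || high_fraction >= 1 ||
      low_fraction + high_fraction >= 1) {
    stop("Fractions must lie in [0, 1) and sum below 1.", call. = FALSE)
  }
  if (nrow(data) == 0L) stop("`data` is empty.", call. = FALSE)
  g <- nrow(data)
  n_low <- floor(low_fraction * g)
  n_high <- floor(high_fraction * g)
  if (n_low + n_high >= g) {
    stop("Filter fractions would remove every transcript.", call. = FALSE)
  }
  cond <- attr(data, "conditions", exact = TRUE)
  summary_stat <- rowMeans(expression_values(data))
  ord <- order(summary_stat, data$transcript_id)
  low_idx <- if (n_low > 0L) ord[seq_len(n_low)] else integer(0)
  high_idx <- if (n_high > 0L) ord[seq.int(g - n_high + 1L, g)] else integer(0)
  removed <- tibble::tibble(
    transcript_id = data$transcript_id[c(low_idx, high_idx)],
    summary = summary_stat[c(low_idx, high_idx)],
    tail = rep(c("low", "high"), c(length(low_idx), length(high_idx)))
  )
  keep <- setdiff(seq_len(g), c(low_idx, high_idx))
  out <- data[sort(keep), , drop = FALSE]
  if (!is.null(cond)) attr(out, "conditions") <- cond
  attr(out, "removed") <- removed
  out
}

#' @describeIn filter_extremes Retrieve the removed-transcript report from a
#'   filtered table.
#' @param x A table returned by `filter_extremes()`.
#' @export
removed_transcripts <- function(x) {
  rem <- attr(x, "removed", exact = TRUE)
  if (is.null(rem)) {
    tibble::tibble(transcript_id = character(), summary = double(),
                   tail = character())
  } else {
    rem
  }
}
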