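#' Plan a rank-proportional read spike-in
#'
#' Samples `k` distinct uniquely mapping (`NH:i:1`) reads uniformly without
#' replacement; the read drawn first gets rank 1, the second rank 2, and so
#' on up to rank `k`. Applying the plan copies each selected read a number
#' of additional times equal to its rank, so a transcript's unique-read
#' count increases by exactly the sum of the ranks of its selected reads —
#' a read-level benchmark in which differential expression is known exactly.
#'
#' @param records SAM record tibble (see [read_sam()]).
#' @param k Number of reads to select (default 100).
#' @param seed Integer seed.
#' @return Tibble `rank`, `row` (index into `records`), `qname`, `rname`.
#' @export
select_spike_reads <- function(records, k = 100L, seed = 1L) {
  eligible <- which(!is.na(records$nh) & records$nh == 1L)
  if (k < 0L) stop("`k` must be >= 0.", call. = FALSE)
  if (length(eligible) < k) {
    stop("Only ", length(eligible), " uniquely mapping reads available; ",
         k, " requested.", call. = FALSE)
  }
  set.seed(seed)
  rows <- if (k == 0L) integer(0) else sample(eligible, k)
  tibble::tibble(rank = seq_len(k), row = rows,
                 qname = records$qname[rows], rname = records$rname[rows])
}

#' Apply a spike plan to a SAM record stream
#'
#' Every selected read of rank `i` gains `i` additional copies (the
#' original is retained), appended after the original records; the header
#' and all untouched records pass through verbatim.
#'
#' @param records SAM record tibble (the control dataset).
#' @param plan A plan from [select_spike_reads()].
#' @return The treatment record tibble, header preserved.
#' @export
apply_spike <- function(records, plan) {
  if (nrow(plan) > 0L) {
    if (any(plan$row > nrow(records)) ||
        any(records$qname[plan$row] != plan$qname)) {
      stop("Spike plan references reads absent from the record stream.",
           call. = FALSE)
    }
  }
  copies <- records[rep(plan$row, times = plan$rank), , drop = FALSE]
  out <- dplyr::bind_rows(records, copies)
  attr(out, "header") <- attr(records, "header", exact = TRUE)
  out
}

#' Ground-truth table for a spike plan
#'
#' Per spiked transcript: the total added count (sum of its reads' ranks),
#' the control unique-read count, and the implied treatment count
#' (`control + added`).
#'
#' @inheritParams apply_spike
#' @return Tibble `transcript_id`, `added`, `control_count`,
#'   `treatment_count`.
#' @export
spike_truth <- function(records, plan) {
  ctrl <- count_reads(records)
  plan |>
    dplyr::count(transcript_id = .data$rname, wt = .data$rank,
                 name = "added") |>
    dplyr::left_join(ctrl, by = "transcript_id") |>
    dplyr::mutate(control_count = dplyr::coalesce(.data$count, 0L),
                  treatment_count = .data$control_count + .data$added) |>
    dplyr::select("transcript_id", "added", "control_count",
                  "treatment_count") |>
    dplyr::arrange(.data$transcript_id)
}
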