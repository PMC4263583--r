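#' Read a Cufflinks-style FPKM tracking table
#'
#' Expects a tab-delimited file with at least a transcript id column, an
#' FPKM point estimate, and lower/upper confidence bounds (the
#' `tracking_id` / `FPKM` / `FPKM_conf_lo` / `FPKM_conf_hi` columns of a
#' Cufflinks `*.fpkm_tracking` file; common alternative spellings are
#' accepted). Rows violating `conf_lo <= fpkm <= conf_hi` are rejected with
#' their line numbers.
#'
#' @param path Path to the tab-delimited file.
#' @param condition Condition label attached to every record.
#' @return Tibble: `transcript_id`, `condition`, `fpkm`, `conf_lo`,
#'   `conf_hi`.
#' @export
read_fpkm_tracking <- function(path, condition) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE, comment = "")
  aliases <- list(
    transcript_id = c("tracking_id", "transcript_id", "id"),
    fpkm = c("FPKM", "fpkm"),
    conf_lo = c("FPKM_conf_lo", "conf_lo", "fpkm_conf_lo"),
    conf_hi = c("FPKM_conf_hi", "conf_hi", "fpkm_conf_hi")
  )
  found <- purrr::map_chr(aliases, function(a) {
    hit <- intersect(a, names(raw))
    if (length(hit) == 0L) NA_character_ else hit[[1L]]
  })
  if (anyNA(found)) {
    stop("Missing required column(s): ",
         paste(names(found)[is.na(found)], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    transcript_id = as.character(raw[[found[["transcript_id"]]]]),
    condition = condition,
    fpkm = as.double(raw[[found[["fpkm"]]]]),
    conf_lo = as.double(raw[[found[["conf_lo"]]]]),
    conf_hi = as.double(raw[[found[["conf_hi"]]]])
  )
  bad <- which(!(out$conf_lo <= out$fpkm & out$fpkm <= out$conf_hi) |
                 !is.finite(out$fpkm))
  if (length(bad) > 0L) {
    stop("Malformed rows (conf_lo <= fpkm <= conf_hi violated) at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  out
}

#' Convert a confidence interval to a variance
#'
#' Treats the interval as a symmetric two-sided normal interval at the given
#' confidence level, so `sd = (conf_hi - conf_lo) / (2 z)` with `z` the
#' corresponding normal quantile (1.959964 at 0.95).
#'
#' @param conf_lo,conf_hi Interval bounds (vectorised).
#' @param level Two-sided confidence level in (0, 1); default 0.95.
#' @return Variance(s); 0 when the bounds coincide (floored downstream).
#' @examples
#' ci_to_variance(0, 3.919928) # 1
#' @export
ci_to_variance <- function(conf_lo, conf_hi, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must be a single value in (0, 1).", call. = FALSE)
  }
  if (any(conf_hi < conf_lo)) {
    stop("`conf_hi` must be >= `conf_lo`.", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  ((conf_hi - conf_lo) / (2 * z))^2
}

#' @describeIn ci_to_variance Add a `variance` column to an FPKM estimate
#'   tibble (as returned by [read_fpkm_tracking()]).
#' @param data Tibble with `conf_lo` and `conf_hi` columns.
#' @export
add_fpkm_variance <- function(data, level = 0.95) {
  dplyr::mutate(data,
                variance = ci_to_variance(.data$conf_lo, .data$conf_hi,
                                          level = level))
}

#' Synthesize normal pseudo-replicates from FPKM point estimates
#'
#' The coupling step between point quantification and the hierarchical
#' model: for each transcript and condition, draws `n_replicates`
#' independent values from `Normal(fpkm, variance)` and assembles them into
#' an expression table with `n_replicates` sample columns per condition.
#' Around 1000 replicates suit noise-free data and around 100 suit noisy
#' data; the count is always the user's choice.
#'
#' Transcripts absent from any condition are dropped (inner join) and
#' reported via the `dropped` attribute. The normal model permits negative
#' draws; set `clamp_negative = TRUE` to truncate them at zero.
#'
#' @param estimates Tibble with `transcript_id`, `condition`, `fpkm` and
#'   either `variance` or both `conf_lo`/`conf_hi` columns (converted at
#'   `conf_level`).
#' @param n_replicates Number of pseudo-replicates per condition (>= 2).
#' @param seed Integer seed; identical seeds give identical output.
#' @param conf_level Confidence level used when deriving variances from
#'   bounds.
#' @param clamp_negative Truncate negative draws at zero (default `FALSE`).
#' @return An expression table (see [as_expression_table()]) with columns
#'   `<condition>_<r>`; attribute `dropped` lists transcripts missing from
#'   at least one condition.
#' @export
synthesize_replicates <- function(estimates, n_replicates = 100L, seed = 1L,
                                  conf_level = 0.95, clamp_negative = FALSE) {
  if (n_replicates < 2L) {
    stop("`n_replicates` must be >= 2: the model needs within-condition ",
         "spread.", call. = FALSE)
  }
  if (!"variance" %in% names(estimates)) {
    estimates <- add_fpkm_variance(estimates, level = conf_level)
  }
  if (any(estimates$variance < 0)) {
    stop("`variance` must be >= 0.", call. = FALSE)
  }
  conditions <- unique(estimates$condition)
  shared <- estimates |>
    dplyr::distinct(.data$transcript_id, .data$condition) |>
    dplyr::count(.data$transcript_id) |>
    dplyr::filter(.data$n == length(conditions)) |>
    dplyr::pull(.data$transcript_id)
  dropped <- setdiff(unique(estimates$transcript_id), shared)
  if (length(dropped) > 0L) {
    message(length(dropped),
            " transcript(s) absent from some condition were dropped.")
  }
  est <- estimates |>
    dplyr::filter(.data$transcript_id %in% shared) |>
    dplyr::arrange(.data$transcript_id)

  set.seed(seed)
  blocks <- lapply(conditions, function(cond) {
    e <- dplyr::filter(est, .data$condition == cond)
    draws <- matrix(
      stats::rnorm(nrow(e) * n_replicates, mean = rep(e$fpkm, n_replicates),
                   sd = rep(sqrt(e$variance), n_replicates)),
      nrow = nrow(e))
    if (clamp_negative) draws <- pmax(draws, 0)
    colnames(draws) <- paste(cond, seq_len(n_replicates), sep = "_")
    tibble::as_tibble(draws)
  })
  ids <- dplyr::filter(est, .data$condition == conditions[[1L]])$transcript_id
  out <- dplyr::bind_cols(tibble::tibble(transcript_id = ids), blocks)
  cond_map <- stats::setNames(rep(conditions, each = n_replicates),
                              unlist(lapply(blocks, names)))
  out <- as_expression_table(out, cond_map)
  attr(out, "dropped") <- dropped
  out
}

#' Write / read an expression table as TSV
#'
#' The condition map travels in a `# conditions:` comment line so the file
#' round-trips without a sidecar.
#'
#' @param data An expression table.
#' @param path File path.
#' @return `write_expression_tsv()` returns `path` invisibly;
#'   `read_expression_tsv()` returns the expression table.
#' @export
write_expression_tsv <- function(data, path) {
  cond <- expression_conditions(data)
  header <- paste0("# conditions: ",
                   paste(names(cond), cond, sep = "=", collapse = "\t"))
  writeLines(header, path)
  readr::write_tsv(data, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# conditions: ")) {
    stop("Missing `# conditions:` header line in ", path, call. = FALSE)
  }
  pairs <- strsplit(sub("^# conditions: ", "", first), "\t")[[1L]]
  kv <- strsplit(pairs, "=", fixed = TRUE)
  cond <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  tbl <- readr::read_tsv(path, skip = 1L, show_col_types = FALSE,
                         progress = FALSE)
  as_expression_table(tbl, cond)
}
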