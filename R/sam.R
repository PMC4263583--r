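#' Minimal SAM text I/O for benchmark construction
#'
#' Reads a plain-text SAM file into a tibble of alignment records, keeping
#' every record's raw line verbatim so that writing is byte-for-byte
#' faithful (header included). Only the mandatory fields and the `NH`
#' auxiliary tag (number of reported alignments; `NH:i:1` marks unique
#' mappers) are interpreted; all other tags pass through opaquely inside the
#' raw line.
#'
#' @param path Path to a SAM text file.
#' @return Tibble with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `nh` (`NA` when absent) and `line` (the verbatim record);
#'   header lines are carried in the `header` attribute.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  recs <- lines[!is_header]
  if (length(recs) == 0L) {
    out <- tibble::tibble(qname = character(), flag = integer(),
                          rname = character(), pos = integer(),
                          mapq = integer(), cigar = character(),
                          nh = integer(), line = character())
  } else {
    fields <- strsplit(recs, "\t", fixed = TRUE)
    nh <- vapply(fields, function(f) {
      tag <- grep("^NH:i:", f[-seq_len(11L)], value = TRUE)
      if (length(tag) == 0L) NA_integer_
      else as.integer(sub("^NH:i:", "", tag[[1L]]))
    }, integer(1))
    out <- tibble::tibble(
      qname = vapply(fields, `[`, "", 1L),
      flag = as.integer(vapply(fields, `[`, "", 2L)),
      rname = vapply(fields, `[`, "", 3L),
      pos = as.integer(vapply(fields, `[`, "", 4L)),
      mapq = as.integer(vapply(fields, `[`, "", 5L)),
      cigar = vapply(fields, `[`, "", 6L),
      nh = nh, line = recs
    )
    if (any(out$pos < 1L, na.rm = TRUE)) {
      stop("SAM positions must be >= 1 (1-based).", call. = FALSE)
    }
  }
  attr(out, "header") <- lines[is_header]
  out
}

#' @rdname read_sam
#' @param records A record tibble as returned by `read_sam()`.
#' @export
write_sam <- function(records, path) {
  header <- attr(records, "header", exact = TRUE)
  writeLines(c(header, records$line), path)
  invisible(path)
}

#' @rdname read_sam
#' @export
sam_header <- function(records) {
  attr(records, "header", exact = TRUE) %||% character(0)
}

#' Count uniquely mapping reads per reference
#'
#' A validation stand-in for an external read counter: the exact multiset
#' count of `NH:i:1` records per reference name.
#'
#' @param records A SAM record tibble (see [read_sam()]).
#' @return Tibble `transcript_id`, `count`, sorted by id.
#' @export
count_reads <- function(records) {
  records |>
    dplyr::filter(!is.na(.data$nh), .data$nh == 1L) |>
    dplyr::count(transcript_id = .data$rname, name = "count") |>
    dplyr::arrange(.data$transcript_id)
}

#' Generate a small synthetic SAM dataset
#'
#' Fixture generator for benchmark experiments: one reference per
#' transcript, the requested number of reads each, random positions and
#' sequences. Reads default to unique mappers (`NH:i:1`); a per-transcript
#' `nh` column in `counts` overrides this.
#'
#' @param counts Tibble with `transcript_id`, `n_reads`, optional `nh`.
#' @param seed Integer seed.
#' @param read_length Read length for the synthetic sequences.
#' @param ref_length Reference length written to the `@SQ` header lines.
#' @return A SAM record tibble (see [read_sam()]).
#' @export
simulate_sam <- function(counts, seed = 1L, read_length = 50L,
                         ref_length = 2000L) {
  set.seed(seed)
  if (!"nh" %in% names(counts)) counts$nh <- 1L
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", counts$transcript_id, "\tLN:", ref_length))
  recs <- purrr::pmap(counts, function(transcript_id, n_reads, nh, ...) {
    if (n_reads == 0L) return(NULL)
    pos <- sample.int(ref_length - read_length, n_reads, replace = TRUE)
    seqs <- vapply(seq_len(n_reads), function(i) {
      paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
            collapse = "")
    }, character(1))
    tibble::tibble(
      qname = sprintf("%s_read%06d", transcript_id, seq_len(n_reads)),
      flag = 0L, rname = transcript_id, pos = as.integer(pos),
      mapq = 255L, cigar = paste0(read_length, "M"),
      nh = as.integer(nh),
      line = sprintf("%s_read%06d\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d",
                     transcript_id, seq_len(n_reads), transcript_id, pos,
                     read_length, seqs, strrep("I", read_length), nh)
    )
  })
  out <- dplyr::bind_rows(recs)
  attr(out, "header") <- header
  out
}
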