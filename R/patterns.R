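#' Declare the expression patterns to compare
#'
#' A pattern assigns every sample an integer group label; samples sharing a
#' label are assumed to share one underlying mean. The first pattern must be
#' the null (all samples in group 1, equivalent expression); within each
#' pattern the labels must be contiguous `1..r`.
#'
#' @param ... Integer vectors, one per pattern, all of the same length
#'   (number of samples). May be named; unnamed patterns get default names
#'   (`null`, `pattern_2`, ...).
#' @return A `pattern_set` object: a named list of integer label vectors.
#' @examples
#' # Four samples, three hypotheses (all-treated vs one-sample vs null):
#' pattern_set(null      = c(1, 1, 1, 1),
#'             etoposide = c(1, 2, 1, 2),
#'             p53       = c(1, 2, 1, 1))
#' @export
pattern_set <- function(...) {
  pats <- lapply(list(...), function(p) as.integer(p))
  if (length(pats) < 1L) stop("Need at least one pattern.", call. = FALSE)
  n <- length(pats[[1L]])
  nm <- names(pats)
  if (is.null(nm)) nm <- rep("", length(pats))
  default <- c("null", paste0("pattern_", seq_along(pats))[-1L])
  nm[nm == ""] <- default[nm == ""]
  names(pats) <- nm
  for (k in seq_along(pats)) {
    p <- pats[[k]]
    if (length(p) != n) {
      stop("All patterns must cover the same number of samples.",
           call. = FALSE)
    }
    r <- max(p)
    if (!setequal(unique(p), seq_len(r))) {
      stop(sprintf("Pattern '%s' labels must be contiguous 1..r.", nm[k]),
           call. = FALSE)
    }
  }
  if (any(pats[[1L]] != 1L)) {
    stop("The first pattern must be the null (all samples in one group).",
         call. = FALSE)
  }
  structure(pats, class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("<pattern_set> ", length(x), " patterns over ",
      length(x[[1L]]), " samples\n", sep = "")
  for (nm in names(x)) cat(sprintf("  %-12s %s\n", nm,
                                   paste(x[[nm]], collapse = " ")))
  invisible(x)
}

#' Null-vs-differential patterns from condition labels
#'
#' Convenience constructor for the two-pattern (equivalent vs differential
#' expression) comparison: the null puts every sample in one group, the DE
#' pattern groups samples by condition.
#'
#' @param conditions Character vector of per-sample condition labels.
#' @return A two-pattern [pattern_set()] named `null`, `DE`.
#' @export
de_patterns <- function(conditions) {
  grp <- as.integer(factor(conditions, levels = unique(conditions)))
  pattern_set(null = rep(1L, length(grp)), DE = grp)
}
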