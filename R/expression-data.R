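#' Attach a sample-to-condition map to an expression table
#'
#' An expression table is an ordinary tibble whose first column is
#' `transcript_id` and whose remaining columns are numeric expression values
#' (FPKM scale), one column per sample. The condition of each sample is
#' carried as a named character vector in the `"conditions"` attribute so the
#' table itself stays pipe-friendly.
#'
#' @param data A data frame with a `transcript_id` column and one numeric
#'   column per sample.
#' @param conditions Named character vector mapping sample column names to
#'   condition labels. Names must match the sample columns of `data`.
#' @return `data` as a tibble with the `conditions` attribute set.
#' @examples
#' tbl <- tibble::tibble(transcript_id = c("t1", "t2"),
#'                       a1 = c(1, 2), a2 = c(1.5, 2.5),
#'                       b1 = c(5, 2), b2 = c(5.5, 1.5))
#' x <- as_expression_table(tbl, c(a1 = "ctrl", a2 = "ctrl",
#'                                 b1 = "treat", b2 = "treat"))
#' expression_conditions(x)
#' @export
as_expression_table <- function(data, conditions) {
  stopifnot(is.data.frame(data))
  if (!"transcript_id" %in% names(data)) {
    stop("`data` must have a `transcript_id` column.", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  sample_cols <- setdiff(names(data), "transcript_id")
  if (length(sample_cols) < 2L) {
    stop("An expression table needs at least 2 sample columns.", call. = FALSE)
  }
  if (is.null(names(conditions)) ||
      !setequal(names(conditions), sample_cols)) {
    stop("`conditions` must be named by the sample columns of `data`.",
         call. = FALSE)
  }
  conditions <- conditions[sample_cols]
  vals <- as.matrix(data[sample_cols])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("All expression values must be finite numerics.", call. = FALSE)
  }
  if (anyDuplicated(data$transcript_id)) {
    stop("`transcript_id` values must be unique.", call. = FALSE)
  }
  attr(data, "conditions") <- conditions
  data
}

#' @rdname as_expression_table
#' @param x An expression table.
#' @export
expression_conditions <- function(x) {
  cond <- attr(x, "conditions", exact = TRUE)
  if (is.null(cond)) {
    stop("No `conditions` attribute; use as_expression_table() or pass ",
         "`conditions` explicitly.", call. = FALSE)
  }
  cond
}

# Numeric matrix of expression values, rownames = transcript ids.
expression_values <- function(data) {
  m <- as.matrix(data[setdiff(names(data), "transcript_id")])
  rownames(m) <- data$transcript_id
  storage.mode(m) <- "double"
  m
}

# Resolve conditions argument: explicit vector wins, else the attribute.
resolve_conditions <- function(data, conditions) {
  if (is.null(conditions)) conditions <- expression_conditions(data)
  sample_cols <- setdiff(names(data), "transcript_id")
  if (is.null(names(conditions))) {
    if (length(conditions) != length(sample_cols)) {
      stop("`conditions` length must match the number of sample columns.",
           call. = FALSE)
    }
    names(conditions) <- sample_cols
  }
  as.character(conditions[sample_cols])
}
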