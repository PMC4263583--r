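#' Negative-binomial read-copy noise for benchmark datasets
#'
#' Sequencing counts across technical replicates are typically
#' overdispersed (variance above the Poisson mean). The benchmark noise
#' model reproduces this at read level: each uniquely mapping read of gene
#' `g` is replicated `y` additional times with `y ~ NB(r_g, p_g)`, where `y`
#' counts successes before `r_g` failures at success probability `p_g`
#' (mean `p r / (1 - p)`, variance `p r / (1 - p)^2` per read). For a gene
#' with `N` original reads the noisy count is `X = N + sum(y)`, with
#' `E(X) = N + p N r / (1 - p)` and `Var(X) = p N r / (1 - p)^2`.
#'
#' `critical_dispersion()` returns the dispersion `r_c = ((1 - p) / p)^2` at
#' which `Var(X) = E(X)` (Poisson-like noise); dispersion above `r_c` gives
#' overdispersion, below it underdispersion. At the critical value both
#' moments equal `N / p`.
#'
#' @param p Success probability in (0, 1).
#' @return `critical_dispersion()`: the critical dispersion `r_c`.
#' @examples
#' critical_dispersion(0.5) # 1
#' @export
critical_dispersion <- function(p) {
  if (any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly in (0, 1).", call. = FALSE)
  }
  ((1 - p) / p)^2
}

#' @describeIn critical_dispersion Draw per-gene noise parameters
#'   guaranteeing overdispersion: `p_g ~ U(0.9, 1)` and
#'   `r_g = c * r_c(p_g)` with `c ~ U(1.2, 2)`, so `r_g > r_c` always.
#' @param gene_ids Character vector of gene/transcript ids.
#' @param seed Integer seed.
#' @export
draw_noise_params <- function(gene_ids, seed = 1L) {
  if (length(gene_ids) == 0L) stop("`gene_ids` is empty.", call. = FALSE)
  set.seed(seed)
  p <- stats::runif(length(gene_ids), 0.9, 1)
  r_c <- critical_dispersion(p)
  r <- stats::runif(length(gene_ids), 1.2, 2) * r_c
  tibble::tibble(transcript_id = as.character(gene_ids),
                 p = p, r = r, r_c = r_c)
}

#' @describeIn critical_dispersion Replicate each uniquely mapping read
#'   `y ~ NB(r_g, p_g)` additional times. Non-unique reads pass through
#'   unchanged; every gene carrying unique reads must have parameters.
#' @param records SAM record tibble (see [read_sam()]).
#' @param params Tibble `transcript_id`, `p`, `r` (e.g. from
#'   `draw_noise_params()`).
#' @export
apply_read_noise <- function(records, params, seed = 1L) {
  unique_idx <- which(!is.na(records$nh) & records$nh == 1L)
  genes <- unique(records$rname[unique_idx])
  missing <- setdiff(genes, params$transcript_id)
  if (length(missing) > 0L) {
    stop("No noise parameters for gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  idx <- match(records$rname[unique_idx], params$transcript_id)
  # rnbinom counts failures before `size` successes at `prob`; with
  # prob = 1 - p it counts successes before r failures at success
  # probability p, i.e. mean p*r/(1-p), variance p*r/(1-p)^2.
  y <- stats::rnbinom(length(unique_idx), size = params$r[idx],
                      prob = 1 - params$p[idx])
  copies <- records[rep(unique_idx, times = y), , drop = FALSE]
  out <- dplyr::bind_rows(records, copies)
  attr(out, "header") <- attr(records, "header", exact = TRUE)
  out
}
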