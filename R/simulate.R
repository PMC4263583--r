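#' Synthetic per-transcript baseline abundance parameters
#'
#' Stand-in for a real quantified transcriptome: per-transcript (mean,
#' variance) pairs with a log-normal mean distribution (median around 60
#' FPKM, spanning roughly three orders of magnitude) and a standard
#' deviation linear in the mean (`sd = 2 + 0.15 * mean`), mimicking the
#' mean-variance coupling of FPKM estimates. Deterministic for a fixed
#' seed; pass your own table of `mean`/`variance` columns to use real
#' estimates instead.
#'
#' @param n_transcripts Number of transcripts.
#' @param seed Integer seed (fixed default so the table is reproducible).
#' @return Tibble `transcript_id`, `mean`, `variance`.
#' @export
base_expression_params <- function(n_transcripts = 1000L, seed = 2013L) {
  set.seed(seed)
  mean <- stats::rlnorm(n_transcripts, meanlog = log(60), sdlog = 1)
  sd <- 2 + 0.15 * mean
  tibble::tibble(
    transcript_id = sprintf("T%05d", seq_len(n_transcripts)),
    mean = mean, variance = sd^2
  )
}

#' Simulate a control/treatment expression study
#'
#' Draws a transcripts-by-replicates control matrix from per-transcript
#' normal distributions at baseline parameters, then a treatment matrix in
#' which a random `de_fraction` of transcripts are over-expressed: half of
#' them with mean shift `+mean_shift`, the other half with
#' `+2 * mean_shift`. Optionally every treatment variance is inflated by
#' `extra_variance`. Only over-expression is simulated.
#'
#' @param n_transcripts Number of transcripts (default 1000).
#' @param de_fraction Fraction of transcripts differentially expressed
#'   (default 0.10).
#' @param mean_shift The shift `x`: half the DE transcripts get `+x`, half
#'   `+2x` (FPKM units).
#' @param extra_variance Variance added to every treatment transcript
#'   (FPKM^2).
#' @param n_replicates Replicates per condition (default 10).
#' @param base_params Tibble with `transcript_id`, `mean`, `variance`;
#'   defaults to [base_expression_params()] truncated/recycled to
#'   `n_transcripts`.
#' @param seed Integer seed.
#' @return A list of class `sim_expression`: `data` (expression table with
#'   conditions `control` / `treatment`) and `truth` (tibble
#'   `transcript_id`, `de`, `shift`).
#' @export
simulate_expression <- function(n_transcripts = 1000L, de_fraction = 0.10,
                                mean_shift = 0, extra_variance = 0,
                                n_replicates = 10L, base_params = NULL,
                                seed = 1L) {
  stopifnot(de_fraction >= 0, de_fraction <= 1, mean_shift >= 0,
            extra_variance >= 0, n_replicates >= 1L)
  if (is.null(base_params)) {
    base_params <- base_expression_params(n_transcripts)
  }
  if (nrow(base_params) < n_transcripts) {
    stop("`base_params` has fewer rows than `n_transcripts`.", call. = FALSE)
  }
  base_params <- base_params[seq_len(n_transcripts), ]
  n_de <- round(de_fraction * n_transcripts)
  if (de_fraction > 0 && n_de < 2L) {
    stop("`de_fraction * n_transcripts` must be >= 2 to split the x / 2x ",
         "groups.", call. = FALSE)
  }
  set.seed(seed)
  de_idx <- sample.int(n_transcripts, n_de)
  shift <- numeric(n_transcripts)
  if (n_de > 0L) {
    half <- n_de %/% 2L
    shift[de_idx[seq_len(half)]] <- mean_shift
    shift[de_idx[seq.int(half + 1L, n_de)]] <- 2 * mean_shift
  }

  draw <- function(mu, var) {
    matrix(stats::rnorm(n_transcripts * n_replicates,
                        mean = rep(mu, n_replicates),
                        sd = rep(sqrt(var), n_replicates)),
           nrow = n_transcripts)
  }
  ctrl <- draw(base_params$mean, base_params$variance)
  trt <- draw(base_params$mean + shift, base_params$variance + extra_variance)
  colnames(ctrl) <- paste0("control_", seq_len(n_replicates))
  colnames(trt) <- paste0("treatment_", seq_len(n_replicates))

  data <- dplyr::bind_cols(
    tibble::tibble(transcript_id = base_params$transcript_id),
    tibble::as_tibble(ctrl), tibble::as_tibble(trt)
  )
  cond <- stats::setNames(rep(c("control", "treatment"),
                              each = n_replicates),
                          c(colnames(ctrl), colnames(trt)))
  truth <- tibble::tibble(transcript_id = base_params$transcript_id,
                          de = shift > 0 | seq_len(n_transcripts) %in%
                            (if (n_de > 0L) de_idx else integer(0)),
                          shift = shift)
  structure(list(data = as_expression_table(data, cond), truth = truth),
            class = "sim_expression")
}

#' Simulate Cufflinks-style FPKM estimate tables
#'
#' Fixture generator for the point-estimate input format: per condition,
#' per transcript, an FPKM value with symmetric 95% normal confidence
#' bounds. A `de_fraction` of transcripts are over-expressed in every
#' non-reference condition by `mean_shift` (half) or `2 * mean_shift`
#' (half), mirroring [simulate_expression()].
#'
#' @inheritParams simulate_expression
#' @param conditions Condition labels; the first is the reference.
#' @return Tibble `transcript_id`, `condition`, `fpkm`, `conf_lo`,
#'   `conf_hi`, with the DE table in the `truth` attribute.
#' @export
simulate_fpkm_estimates <- function(n_transcripts = 20L, de_fraction = 0.10,
                                    mean_shift = 50,
                                    conditions = c("control", "treatment"),
                                    base_params = NULL, seed = 1L) {
  if (is.null(base_params)) {
    base_params <- base_expression_params(n_transcripts)
  }
  base_params <- base_params[seq_len(n_transcripts), ]
  set.seed(seed)
  n_de <- round(de_fraction * n_transcripts)
  de_idx <- sample.int(n_transcripts, n_de)
  shift <- numeric(n_transcripts)
  if (n_de > 0L) {
    half <- n_de %/% 2L
    shift[de_idx[seq_len(half)]] <- mean_shift
    if (half < n_de) shift[de_idx[seq.int(half + 1L, n_de)]] <- 2 * mean_shift
  }
  z <- stats::qnorm(0.975)
  # point estimates are generated precise relative to their declared
  # intervals (noise at one fifth of the per-transcript sd), so that the
  # planted shifts, not estimation noise, dominate downstream calls
  out <- purrr::map_dfr(seq_along(conditions), function(ci) {
    mu <- base_params$mean + if (ci == 1L) 0 else shift
    fpkm <- stats::rnorm(n_transcripts, mu, sqrt(base_params$variance) / 5)
    half_width <- z * sqrt(base_params$variance)
    tibble::tibble(transcript_id = base_params$transcript_id,
                   condition = conditions[[ci]], fpkm = fpkm,
                   conf_lo = fpkm - half_width, conf_hi = fpkm + half_width)
  })
  attr(out, "truth") <- tibble::tibble(
    transcript_id = base_params$transcript_id, de = shift > 0, shift = shift)
  out
}

#' @rdname simulate_fpkm_estimates
#' @param data An estimate tibble from `simulate_fpkm_estimates()`
#'   (one condition's rows).
#' @param path Output path.
#' @return `write_fpkm_tracking()` returns `path` invisibly.
#' @export
write_fpkm_tracking <- function(data, path) {
  readr::write_tsv(
    dplyr::transmute(data, tracking_id = .data$transcript_id,
                     FPKM = .data$fpkm, FPKM_conf_lo = .data$conf_lo,
                     FPKM_conf_hi = .data$conf_hi),
    path, progress = FALSE)
  invisible(path)
}
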