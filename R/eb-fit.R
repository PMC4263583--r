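#' EM settings for the empirical Bayes fit
#'
#' @param tol Relative marginal log-likelihood change below which EM stops.
#' @param max_iter Maximum EM iterations.
#' @param mix_floor Lower bound kept on mixing proportions during EM so no
#'   pattern becomes an absorbing zero state; the final reported mix is the
#'   unfloored posterior average.
#' @return A list of class `eb_control`.
#' @export
eb_control <- function(tol = 1e-6, max_iter = 1000L, mix_floor = 1e-6) {
  stopifnot(tol > 0, max_iter >= 1L, mix_floor >= 0, mix_floor < 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 mix_floor = mix_floor), class = "eb_control")
}

# Per-pattern, per-group sufficient statistics of the data: for group g of
# pattern k, the per-transcript sums and sums of squares over the group's
# sample columns. Computed once; the log-likelihood at any (mu0, tau0_sq)
# then costs O(G) per group.
pattern_suffstats <- function(values, patterns) {
  lapply(patterns, function(p) {
    lapply(split(seq_along(p), p), function(cols) {
      v <- values[, cols, drop = FALSE]
      list(n = length(cols), s = rowSums(v), ss = rowSums(v^2))
    })
  })
}

# G x K matrix of per-transcript log densities under each pattern.
pattern_loglik <- function(stats, mu0, tau0_sq, sigma_sq) {
  g <- length(stats[[1L]][[1L]]$s)
  L <- vapply(stats, function(groups) {
    Reduce(`+`, lapply(groups, function(grp) {
      cs_log_density(grp$ss - 2 * mu0 * grp$s + grp$n * mu0^2,
                     grp$s - grp$n * mu0, grp$n, sigma_sq, tau0_sq)
    }))
  }, numeric(g))
  matrix(L, nrow = g, ncol = length(stats))
}

# Row-wise log-sum-exp.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

# Pooled within-condition sample variance per transcript (the plug-in
# observation variance), floored to keep the covariance non-singular.
# With few samples the raw per-transcript variances are noisy enough to
# inflate the fitted DE proportion, so by default they are shrunk toward a
# common prior variance (empirical Bayes moderation, limma::squeezeVar)
# before being plugged in.
pooled_sigma_sq <- function(values, conditions, floor = 1e-8,
                            moderate = TRUE) {
  groups <- split(seq_along(conditions), conditions)
  df <- sum(vapply(groups, length, integer(1)) - 1L)
  if (df < 1L) {
    stop("Pooled variance needs at least one condition with >= 2 samples.",
         call. = FALSE)
  }
  ss <- Reduce(`+`, lapply(groups, function(cols) {
    v <- values[, cols, drop = FALSE]
    rowSums((v - rowMeans(v))^2)
  }))
  v <- ss / df
  if (moderate) {
    v <- tryCatch(limma::squeezeVar(v, df = df)$var.post,
                  error = function(e) v)
  }
  pmax(v, floor)
}

# KKT solution of max sum(c_k log p_k) s.t. sum(p)=1, p >= floor.
floor_simplex <- function(p, floor) {
  if (floor <= 0 || all(p >= floor)) return(p / sum(p))
  p <- p / sum(p)
  fixed <- rep(FALSE, length(p))
  repeat {
    low <- !fixed & p < floor
    if (!any(low)) break
    fixed <- fixed | low
    p[fixed] <- floor
    free <- !fixed
    p[free] <- p[free] / sum(p[free]) * (1 - floor * sum(fixed))
  }
  p
}

#' Fit the empirical Bayes normal-normal mixture by EM
#'
#' Fits the hierarchical model in which each transcript's expression values
#' follow `X | mu ~ N(mu, sigma_j^2)` with group means drawn from the shared
#' prior `N(mu0, tau0_sq)`, and each transcript belongs to expression
#' pattern `k` with prior probability `mix[k]`. The E-step computes posterior
#' pattern probabilities; the M-step updates `mix` as the posterior average
#' (kept above a small floor) and `(mu0, tau0_sq)` by bounded quasi-Newton
#' maximization of the expected complete-data log-likelihood on
#' `(mu0, log tau0_sq)`, started at the current iterate so the marginal
#' log-likelihood never decreases.
#'
#' Per-transcript observation variances `sigma_j^2` default to the pooled
#' within-condition sample variance of the data, shrunk toward a common
#' prior variance by empirical Bayes moderation (`limma::squeezeVar`): with
#' few samples the raw per-transcript variances are noisy, and that noise
#' systematically inflates the fitted DE proportion. Set
#' `moderate_var = FALSE` for the raw plug-in, or supply externally
#' estimated variances (e.g. from confidence intervals of the abundance
#' estimates) via `sigma_sq`.
#'
#' @param data Expression table (see [as_expression_table()]): a tibble with
#'   `transcript_id` plus one numeric column per sample.
#' @param patterns A [pattern_set()]; the first pattern must be the null.
#' @param conditions Per-sample condition labels; defaults to the table's
#'   `conditions` attribute. Used only to pool the plug-in variances.
#' @param sigma_sq Optional per-transcript observation variances (length
#'   `nrow(data)` or scalar). Overrides the pooled plug-in.
#' @param moderate_var Shrink the pooled plug-in variances toward a common
#'   prior variance (default `TRUE`); ignored when `sigma_sq` is supplied.
#' @param log_transform If `TRUE`, model `log1p` of the values instead of
#'   the raw FPKM scale. Off by default.
#' @param control An [eb_control()].
#' @return An object of class `eb_fit` with elements `mu0`, `tau0_sq`,
#'   `mix`, `sigma_sq`, `posteriors` (tibble: `transcript_id`, one column
#'   per pattern, and the maximum-posterior `call`), `log_likelihood_trace`,
#'   `converged`, `n_iterations`, `patterns`.
#' @seealso [posterior_probabilities()], [rank_by_pattern()],
#'   [tidy.eb_fit()], [glance.eb_fit()]
#' @export
eb_fit <- function(data, patterns, conditions = NULL, sigma_sq = NULL,
                   moderate_var = TRUE, log_transform = FALSE,
                   control = eb_control()) {
  stopifnot(inherits(patterns, "pattern_set"), inherits(control, "eb_control"))
  values <- expression_values(data)
  if (log_transform) values <- log1p(values)
  n_samples <- ncol(values)
  if (length(patterns[[1L]]) != n_samples) {
    stop("Patterns cover ", length(patterns[[1L]]),
         " samples but the data has ", n_samples, ".", call. = FALSE)
  }
  if (n_samples < 2L) stop("Need at least 2 samples.", call. = FALSE)
  if (length(patterns) < 2L) {
    stop("Need at least 2 patterns (the null plus one alternative).",
         call. = FALSE)
  }
  if (nrow(values) < length(patterns)) {
    stop("Fewer transcripts than patterns; the mixture is unidentifiable.",
         call. = FALSE)
  }

  if (is.null(sigma_sq)) {
    cond <- resolve_conditions(data, conditions)
    sigma_sq <- pooled_sigma_sq(values, cond, moderate = moderate_var)
  } else {
    sigma_sq <- rep_len(as.double(sigma_sq), nrow(values))
    if (any(sigma_sq <= 0)) stop("`sigma_sq` must be > 0.", call. = FALSE)
  }

  stats <- pattern_suffstats(values, patterns)
  K <- length(patterns)
  m <- K - 1L

  # Initialization: grand mean, between-transcript variance, mild null mass.
  mu0 <- mean(values)
  tau0_sq <- max(stats::var(rowMeans(values)), 1e-8)
  mix <- c(0.95, rep(0.05 / m, m))

  neg_q <- function(par, z) {
    L <- pattern_loglik(stats, par[1L], exp(par[2L]), sigma_sq)
    -sum(z * L)
  }

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    L <- pattern_loglik(stats, mu0, tau0_sq, sigma_sq)
    lp <- sweep(L, 2L, log(mix), `+`)
    ll_j <- row_logsumexp(lp)
    if (any(!is.finite(ll_j))) {
      bad <- rownames(values)[which(!is.finite(ll_j))[1L]]
      stop("All pattern densities vanished for transcript '", bad, "'.",
           call. = FALSE)
    }
    trace <- c(trace, sum(ll_j))
    z <- exp(lp - ll_j)

    if (iter > 1L) {
      rel <- abs(trace[iter] - trace[iter - 1L]) /
        (abs(trace[iter - 1L]) + .Machine$double.eps)
      if (rel < control$tol) { converged <- TRUE; break }
    }
    if (iter >= control$max_iter) break

    mix <- floor_simplex(colMeans(z), control$mix_floor)
    opt <- stats::optim(c(mu0, log(tau0_sq)), neg_q, z = z,
                        method = "L-BFGS-B",
                        lower = c(-Inf, -40), upper = c(Inf, 40))
    mu0 <- opt$par[1L]
    tau0_sq <- exp(opt$par[2L])
  }
  if (!converged) {
    warning("EM did not converge in ", control$max_iter, " iterations.",
            call. = FALSE)
  }

  post <- z / rowSums(z)
  colnames(post) <- names(patterns)
  posteriors <- tibble::tibble(transcript_id = rownames(values)) |>
    dplyr::bind_cols(tibble::as_tibble(post)) |>
    dplyr::mutate(call = names(patterns)[max.col(post, ties.method = "first")])

  structure(list(
    mu0 = mu0, tau0_sq = tau0_sq,
    mix = stats::setNames(colMeans(z), names(patterns)),
    sigma_sq = stats::setNames(sigma_sq, rownames(values)),
    posteriors = posteriors,
    log_likelihood_trace = trace,
    converged = converged, n_iterations = iter,
    patterns = patterns
  ), class = "eb_fit")
}

#' @export
print.eb_fit <- function(x, ...) {
  cat("<eb_fit> ", nrow(x$posteriors), " transcripts, ",
      length(x$patterns), " patterns\n", sep = "")
  cat(sprintf("  mu0 = %.4g, tau0_sq = %.4g\n", x$mu0, x$tau0_sq))
  cat("  mix:", paste(sprintf("%s=%.4g", names(x$mix), x$mix),
                      collapse = ", "), "\n")
  cat(sprintf("  log-likelihood %.4f after %d iterations (%s)\n",
              utils::tail(x$log_likelihood_trace, 1L), x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Posterior pattern probabilities at fixed hyperparameters
#'
#' Evaluates, for every transcript, the posterior probability of each
#' expression pattern by Bayes' formula
#' `P(pattern k | x) = mix[k] f_k(x) / sum_l mix[l] f_l(x)`,
#' with all densities combined on the log scale (log-sum-exp).
#'
#' @inheritParams eb_fit
#' @param mu0,tau0_sq Prior mean and variance of group means.
#' @param mix Mixing proportions, one per pattern, summing to 1.
#' @param sigma_sq Per-transcript observation variance (scalar recycled).
#' @return Tibble: `transcript_id`, one probability column per pattern, and
#'   the maximum-posterior `call`. Rows sum to 1.
#' @export
posterior_probabilities <- function(data, patterns, mu0, tau0_sq, mix,
                                    sigma_sq) {
  stopifnot(inherits(patterns, "pattern_set"))
  if (length(mix) != length(patterns)) {
    stop("`mix` must have one entry per pattern.", call. = FALSE)
  }
  if (abs(sum(mix) - 1) > 1e-12 || any(mix < 0) || any(mix > 1)) {
    stop("`mix` entries must lie in [0,1] and sum to 1.", call. = FALSE)
  }
  values <- expression_values(data)
  sigma_sq <- rep_len(as.double(sigma_sq), nrow(values))
  stats <- pattern_suffstats(values, patterns)
  L <- pattern_loglik(stats, mu0, tau0_sq, sigma_sq)
  lp <- sweep(L, 2L, log(mix), `+`)
  ll_j <- row_logsumexp(lp)
  if (any(!is.finite(ll_j))) {
    bad <- rownames(values)[which(!is.finite(ll_j))[1L]]
    stop("All pattern densities vanished for transcript '", bad, "'.",
         call. = FALSE)
  }
  post <- exp(lp - ll_j)
  post <- post / rowSums(post)
  colnames(post) <- names(patterns)
  tibble::tibble(transcript_id = rownames(values)) |>
    dplyr::bind_cols(tibble::as_tibble(post)) |>
    dplyr::mutate(call = names(patterns)[max.col(post, ties.method = "first")])
}

#' Rank transcripts by posterior probability of one pattern
#'
#' Transcripts with higher posterior probability are more likely to follow
#' the pattern; a typical selection rule keeps transcripts with posterior
#' above 0.99. Ties are broken lexicographically by transcript id so the
#' ranking is deterministic.
#'
#' @param fit An [eb_fit()] result.
#' @param pattern Pattern name or index (1-based into the pattern set).
#' @return Tibble `transcript_id`, `posterior`, sorted by decreasing
#'   posterior.
#' @export
rank_by_pattern <- function(fit, pattern) {
  stopifnot(inherits(fit, "eb_fit"))
  nm <- if (is.numeric(pattern)) names(fit$patterns)[pattern] else pattern
  if (is.na(nm) || !nm %in% names(fit$patterns)) {
    stop("Unknown pattern: ", pattern, call. = FALSE)
  }
  fit$posteriors |>
    dplyr::transmute(transcript_id = .data$transcript_id,
                     posterior = .data[[nm]]) |>
    dplyr::arrange(dplyr::desc(.data$posterior), .data$transcript_id)
}
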