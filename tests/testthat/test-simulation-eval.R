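# Simulation designs, ROC / true-discovery evaluation, delta method, Fano.

test_that("the simulator plants the declared over-expression", {
  sim <- simulate_expression(n_transcripts = 500L, mean_shift = 50,
                             n_replicates = 10L, seed = 1L)
  cond <- expression_conditions(sim$data)
  ctrl <- as.matrix(sim$data[names(cond)[cond == "control"]])
  trt <- as.matrix(sim$data[names(cond)[cond == "treatment"]])
  expect_equal(sum(sim$truth$de), 50L)
  bp <- base_expression_params(500L)
  for (s in c(50, 100)) {
    idx <- which(sim$truth$shift == s)
    diffs <- rowMeans(trt[idx, ]) - rowMeans(ctrl[idx, ])
    se <- sqrt(2 * bp$variance[idx] / 10)
    expect_true(all(abs(diffs - s) < 3.5 * se))
  }
  # non-DE transcripts have no shift
  idx0 <- which(!sim$truth$de)
  expect_lt(abs(mean(rowMeans(trt[idx0, ]) - rowMeans(ctrl[idx0, ]))), 1)
  # determinism
  sim2 <- simulate_expression(n_transcripts = 500L, mean_shift = 50,
                              n_replicates = 10L, seed = 1L)
  expect_identical(sim$data, sim2$data)
  expect_error(simulate_expression(n_transcripts = 10L, de_fraction = 0.1),
               ">= 2")
})

test_that("roc_curve matches brute-force threshold enumeration", {
  brute_force_roc <- function(s, l) {
    ths <- sort(unique(s), decreasing = TRUE)
    t(vapply(ths, function(th) {
      c(fpr = sum(s >= th & !l) / sum(!l),
        tpr = sum(s >= th & l) / sum(l))
    }, c(fpr = 0, tpr = 0)))
  }
  set.seed(21)
  for (i in 1:5) {
    g <- sample(20:200, 1)
    # coarse scores force ties
    df <- tibble::tibble(score = round(runif(g), 2),
                         de = runif(g) < 0.3)
    if (length(unique(df$de)) < 2) next
    rc <- roc_curve(df, score, de)
    bf <- brute_force_roc(df$score, df$de)
    expect_equal(rc$fpr[-1], unname(bf[, "fpr"]))
    expect_equal(rc$tpr[-1], unname(bf[, "tpr"]))
  }
})

test_that("roc_curve handles separation, permutation null and total ties", {
  sep <- tibble::tibble(score = c(rep(1, 5), rep(0, 5)),
                        de = rep(c(TRUE, FALSE), each = 5))
  expect_equal(roc_auc(roc_curve(sep, score, de)), 1)
  # random labels on 5000 transcripts: AUC near 1/2
  set.seed(22)
  nul <- tibble::tibble(score = runif(5000), de = sample(c(TRUE, FALSE),
                                                         5000, TRUE))
  expect_lt(abs(roc_auc(roc_curve(nul, score, de)) - 0.5), 0.03)
  # all-equal scores collapse to the diagonal
  tie <- tibble::tibble(score = rep(0.7, 100),
                        de = rep(c(TRUE, FALSE), 50))
  rc <- roc_curve(tie, score, de)
  expect_equal(roc_auc(rc), 0.5)
  expect_equal(nrow(rc), 2L)
  expect_error(roc_curve(tie[tie$de, ], score, de), "Both classes")
})

test_that("roc_curve agrees with an established AUC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  df <- tibble::tibble(score = rnorm(300) + rep(c(1, 0), c(60, 240)),
                       de = rep(c(TRUE, FALSE), c(60, 240)))
  ours <- roc_auc(roc_curve(df, score, de))
  theirs <- as.numeric(pROC::auc(pROC::roc(df$de, df$score, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("true-discovery curves count top-N hits", {
  ranked <- tibble::tibble(transcript_id = sprintf("t%03d", 1:100))
  truth_first <- ranked$transcript_id[1:10]
  tdc <- true_discovery_curve(ranked, truth_first)
  expect_equal(tdc$n_correct, pmin(1:100, 10L))
  truth_last <- ranked$transcript_id[91:100]
  tdc2 <- true_discovery_curve(ranked, truth_last)
  expect_true(all(tdc2$n_correct[1:90] == 0L))
  expect_equal(tail(tdc2$n_correct, 1), 10L)
  # exhaustion: at N = total the curve equals |truth|, whatever the ranking
  set.seed(24)
  shuffled <- ranked[sample(100), ]
  truth <- sample(ranked$transcript_id, 79)
  expect_equal(tail(true_discovery_curve(shuffled, truth)$n_correct, 1), 79L)
  expect_true(all(diff(true_discovery_curve(shuffled, truth)$n_correct) >= 0))
  expect_error(true_discovery_curve(ranked, truth, max_n = 101), "exceeds")
})

test_that("delta-method variance of a product is exact and realised", {
  expect_equal(product_delta_variance(2, 3, 1, 1, 0), 13)
  expect_equal(product_delta_variance(5, 7, 2, 0, 0), 7^2 * 4)
  expect_error(product_delta_variance(1, 1, -1, 1), "sigma")
  expect_error(product_delta_variance(1, 1, 1, 1, rho = 2), "rho")
  # Monte Carlo: sqrt(n)(theta_hat*eta_hat - theta*eta) ~ N(0, gamma^2)
  theta <- 4; eta <- 2.5; s1 <- 1.2; s2 <- 0.8; rho <- 0.4
  n <- 1e4; reps <- 1e5
  set.seed(25)
  z1 <- rnorm(reps); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(reps)
  th <- theta + s1 * z1 / sqrt(n)
  et <- eta + s2 * z2 / sqrt(n)
  realised <- var(sqrt(n) * (th * et - theta * eta))
  expect_lt(abs(realised / product_delta_variance(theta, eta, s1, s2, rho)
                - 1), 0.05)
})

test_that("Fano regression flags overdispersion and not Poisson noise", {
  set.seed(26)
  # Poisson null: Fano near 1, slope near 0
  g <- 10000L; reps <- 10L
  mu <- rlnorm(g, log(50), 0.8)
  pois <- matrix(rpois(g * reps, rep(mu, reps)), g)
  rownames(pois) <- sprintf("g%05d", 1:g)
  fr <- fano_regression(pois)
  expect_lt(abs(mean(fr$fano) - 1), 0.02)
  se_slope <- summary(attr(fr, "fit"))$coefficients["mean", "Std. Error"]
  expect_lt(abs(attr(fr, "slope")), 3 * se_slope)
  # NB per-read copy noise: Fano factors above 1, growing with the mean
  n0 <- rpois(500L, 100L)
  prm <- draw_noise_params(sprintf("n%03d", 1:500), seed = 27L)
  nb <- vapply(seq_len(8L), function(r) {
    y <- rnbinom(500L, size = n0 * prm$r, prob = 1 - prm$p)
    n0 + y
  }, numeric(500L))
  rownames(nb) <- prm$transcript_id
  fr2 <- fano_regression(nb)
  expect_gt(mean(fr2$fano), 1)
  expect_gt(attr(fr2, "slope"), 0)
  # constant counts give Fano 0; zero-mean genes are excluded
  const <- matrix(5, 4, 3)
  const[4, ] <- 0
  rownames(const) <- c("a", "b", "c", "z")
  fr3 <- fano_regression(const)
  expect_equal(fr3$fano, rep(0, 3))
  expect_identical(attr(fr3, "excluded"), "z")
  expect_error(fano_regression(matrix(0, 3, 3)), "zero")
  # first_k restricts the regression, as in low/high-mean panels
  fr4 <- fano_regression(nb, first_k = 100L)
  expect_false(identical(attr(fr4, "slope"), attr(fr2, "slope")))
})

test_that("evaluation result objects plot", {
  df <- tibble::tibble(score = c(1, 2, 3, 4), de = c(FALSE, FALSE, TRUE,
                                                     TRUE))
  expect_s3_class(ggplot2::autoplot(roc_curve(df, score, de)), "ggplot")
  ranked <- tibble::tibble(transcript_id = letters[1:4])
  expect_s3_class(ggplot2::autoplot(true_discovery_curve(ranked, c("a"))),
                  "ggplot")
})
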