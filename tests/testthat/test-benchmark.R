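# Read-level benchmark construction: SAM I/O, spike-in, NB noise.

test_that("SAM files round-trip byte-for-byte", {
  sam <- simulate_sam(tibble::tibble(transcript_id = c("tA", "tB"),
                                     n_reads = c(5L, 3L)), seed = 1L)
  p1 <- withr::local_tempfile(fileext = ".sam")
  p2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(sam, p1)
  write_sam(read_sam(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
  # unknown tags and header lines pass through verbatim
  p3 <- withr::local_tempfile(fileext = ".sam")
  lines <- c("@HD\tVN:1.6", "@CO\tfree text comment",
             "r1\t0\ttA\t7\t60\t5M\t*\t0\t0\tACGTA\tIIIII\tNH:i:1\tXZ:Z:x,y",
             "r2\t0\ttA\t9\t60\t5M\t*\t0\t0\tACGTA\tIIIII\tNH:i:2")
  writeLines(lines, p3)
  rec <- read_sam(p3)
  expect_identical(rec$nh, c(1L, 2L))
  expect_identical(rec$pos, c(7L, 9L))
  p4 <- withr::local_tempfile(fileext = ".sam")
  write_sam(rec, p4)
  expect_identical(readLines(p4), lines)
  # empty file
  p5 <- withr::local_tempfile(fileext = ".sam")
  writeLines("@HD\tVN:1.6", p5)
  expect_equal(nrow(read_sam(p5)), 0L)
})

test_that("count_reads counts exactly the uniquely mapping reads", {
  sam <- simulate_sam(tibble::tibble(
    transcript_id = c("tA", "tB", "tC"),
    n_reads = c(4L, 2L, 3L),
    nh = c(1L, 2L, 1L)), seed = 2L)
  cnt <- count_reads(sam)
  expect_identical(cnt$transcript_id, c("tA", "tC"))
  expect_identical(cnt$count, c(4L, 3L))
  expect_equal(nrow(count_reads(sam[0, ])), 0L)
})

test_that("spike selection is uniform over unique mappers, seeded", {
  sam <- simulate_sam(tibble::tibble(
    transcript_id = c("tA", "tB", "tMulti"),
    n_reads = c(6L, 4L, 5L),
    nh = c(1L, 1L, 3L)), seed = 3L)
  plan <- select_spike_reads(sam, k = 10L, seed = 1L)
  # exactly the eligible reads, ranks a permutation of 1..k
  expect_setequal(plan$rank, 1:10)
  expect_false("tMulti" %in% plan$rname)
  expect_equal(anyDuplicated(plan$row), 0L)
  expect_identical(select_spike_reads(sam, 10L, seed = 1L), plan)
  expect_equal(nrow(select_spike_reads(sam, 0L, seed = 1L)), 0L)
  expect_error(select_spike_reads(sam, 11L, seed = 1L), "10 uniquely")
  big <- simulate_sam(tibble::tibble(transcript_id = "tA",
                                     n_reads = 10000L), seed = 4L)
  p1 <- select_spike_reads(big, 100L, seed = 1L)
  p2 <- select_spike_reads(big, 100L, seed = 2L)
  expect_false(identical(p1$row, p2$row))
})

test_that("spike application adds rank-many copies and conserves counts", {
  # transcript with 86 unique reads and one selected read of rank 11 -> 97
  # (the worked arithmetic of the published benchmark table)
  sam <- simulate_sam(tibble::tibble(
    transcript_id = c("tx086", "tx102", "tx093"),
    n_reads = c(86L, 102L, 93L)), seed = 5L)
  pick <- function(rn, ranks) {
    rows <- which(sam$rname == rn)[seq_along(ranks)]
    tibble::tibble(rank = ranks, row = rows,
                   qname = sam$qname[rows], rname = rn)
  }
  plan <- dplyr::arrange(dplyr::bind_rows(pick("tx086", 11L),
                                          pick("tx102", c(5L, 9L)),
                                          pick("tx093", c(40L, 41L))),
                         rank)
  treat <- apply_spike(sam, plan)
  cnt <- count_reads(treat)
  expect_identical(cnt$count[cnt$transcript_id == "tx086"], 97L)
  expect_identical(cnt$count[cnt$transcript_id == "tx102"], 116L)
  expect_identical(cnt$count[cnt$transcript_id == "tx093"], 174L)
  # global conservation: treatment total = control total + sum of ranks
  expect_equal(nrow(treat), nrow(sam) + sum(plan$rank))
  truth <- spike_truth(sam, plan)
  expect_identical(truth$added, c(81L, 11L, 14L)[order(c("tx093", "tx086",
                                                         "tx102"))])
  expect_equal(truth$treatment_count, truth$control_count + truth$added)
  expect_identical(
    dplyr::inner_join(truth, cnt, by = "transcript_id")$treatment_count,
    dplyr::inner_join(truth, cnt, by = "transcript_id")$count)
})

test_that("small spike plans behave per the copy-count contract", {
  sam <- simulate_sam(tibble::tibble(transcript_id = "tA",
                                     n_reads = 10L), seed = 6L)
  rows <- which(sam$rname == "tA")[1:2]
  plan <- tibble::tibble(rank = c(3L, 4L), row = rows,
                         qname = sam$qname[rows], rname = "tA")
  treat <- apply_spike(sam, plan)
  expect_identical(count_reads(treat)$count, 17L)
  expect_identical(spike_truth(sam, plan)$added, 7L)
  # empty plan -> byte-identical output
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_sam(sam, p1)
  write_sam(apply_spike(sam, plan[0, ]), p2)
  expect_identical(readLines(p1), readLines(p2))
  bad <- plan; bad$qname <- c("ghost", "ghost2")
  expect_error(apply_spike(sam, bad), "absent")
})

test_that("critical dispersion follows ((1-p)/p)^2", {
  expect_equal(critical_dispersion(0.5), 1)
  expect_equal(critical_dispersion(0.9), (1 / 9)^2, tolerance = 1e-9)
  p <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(critical_dispersion(p)) < 0))
  expect_error(critical_dispersion(0), "strictly")
  expect_error(critical_dispersion(1), "strictly")
})

test_that("noise parameter draws respect the overdispersion scheme", {
  prm <- draw_noise_params(sprintf("g%05d", 1:10000), seed = 9L)
  expect_true(all(prm$p > 0.9 & prm$p < 1))
  expect_true(all(prm$r / prm$r_c > 1.2 & prm$r / prm$r_c < 2))
  expect_equal(prm$r_c, critical_dispersion(prm$p))
  # uniform-moment check on p: mean 0.95, sd 0.1/sqrt(12)
  se <- (0.1 / sqrt(12)) / sqrt(10000)
  expect_lt(abs(mean(prm$p) - 0.95), 3 * se)
  expect_identical(draw_noise_params(c("a", "b"), seed = 1L),
                   draw_noise_params(c("a", "b"), seed = 1L))
  expect_error(draw_noise_params(character(0)), "empty")
})

test_that("read noise reproduces the NB moment formulas", {
  n_reads <- 200L
  p <- 0.95; r <- 0.05
  sam <- simulate_sam(tibble::tibble(transcript_id = "gX",
                                     n_reads = n_reads), seed = 10L)
  prm <- tibble::tibble(transcript_id = "gX", p = p, r = r)
  reps <- 500L
  counts <- vapply(seq_len(reps), function(i) {
    noisy <- apply_read_noise(sam, prm, seed = 1000L + i)
    count_reads(noisy)$count
  }, integer(1))
  e_x <- n_reads + p * n_reads * r / (1 - p)
  v_x <- p * n_reads * r / (1 - p)^2
  # SE of the sample variance from the exact NB fourth central moment
  R <- n_reads * r
  mu4 <- p * R * (1 + 4 * p + p^2) / (1 - p)^4 + 3 * v_x^2
  se_mean <- sqrt(v_x / reps)
  se_var <- sqrt((mu4 - v_x^2 * (reps - 3) / (reps - 1)) / reps)
  expect_lt(abs(mean(counts) - e_x), 3 * se_mean)
  expect_lt(abs(var(counts) - v_x), 3 * se_var)
  # missing parameters must error, zero-dispersion limit is the identity
  expect_error(apply_read_noise(sam, prm[0, ], seed = 1L), "No noise")
  still <- apply_read_noise(sam, tibble::tibble(transcript_id = "gX",
                                                p = 0.95, r = 1e-12),
                            seed = 1L)
  expect_identical(still$line, sam$line)
})

test_that("the critical dispersion is the Poisson boundary", {
  n_reads <- 100L
  p <- 0.92
  sam <- simulate_sam(tibble::tibble(transcript_id = "gY",
                                     n_reads = n_reads), seed = 11L)
  reps <- 800L
  fano_at <- function(r) {
    prm <- tibble::tibble(transcript_id = "gY", p = p, r = r)
    counts <- vapply(seq_len(reps), function(i) {
      count_reads(apply_read_noise(sam, prm, seed = 2000L + i))$count
    }, integer(1))
    var(counts) / mean(counts)
  }
  f_crit <- fano_at(critical_dispersion(p))
  expect_lt(abs(f_crit - 1), 3 * sqrt(2 / (reps - 1)))
  # the sampling scheme guarantees overdispersion
  prm <- draw_noise_params("gY", seed = 12L)
  f_over <- fano_at(prm$r)
  expect_gt(f_over, 1)
})
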