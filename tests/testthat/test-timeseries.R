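test_that("median profiles reference the baseline day", {
  # single replicate: profile equals the input row
  m <- tibble::tibble(gene_id = c("g1", "g2"),
                      d4_r1 = c(0, 1), d8_r1 = c(1, 1), d12_r1 = c(3, 1))
  prof <- median_profile(m, time = c(4, 8, 12))
  expect_equal(unname(prof$profile["g1", ]), c(0, 1, 3))
  expect_equal(unname(prof$delta[, "d4"]), c(0, 0))
  expect_equal(unname(prof$max_abs_change), c(3, 0))

  # replicate median is robust to one outlier
  r <- tibble::tibble(gene_id = "g1",
                      d4_r1 = 0, d4_r2 = 0, d4_r3 = 0,
                      d8_r1 = 1, d8_r2 = 2, d8_r3 = 9)
  pr <- median_profile(r, time = c(4, 4, 4, 8, 8, 8))
  expect_equal(unname(pr$profile["g1", "d8"]), 2)

  expect_error(median_profile(m, time = c(4, 8, 12), baseline = 2),
               "not one of the time points")
})

test_that("fold-change DEG calls use a strict log2(2.5) threshold", {
  delta <- log2(2.5)
  m <- tibble::tibble(gene_id = c("at_cut", "above", "flat"),
                      d4_r1 = c(0, 0, 0.2),
                      d8_r1 = c(delta, 3, 0.2),
                      d12_r1 = c(0, 1, 0.2))
  calls <- call_ts_degs(median_profile(m, c(4, 8, 12)))
  expect_equal(calls$is_deg, c(FALSE, TRUE, FALSE))
  expect_error(call_ts_degs(median_profile(m, c(4, 8, 12)), fc_cutoff = 1),
               "exceed 1")

  # adding a gene-wise constant leaves calls unchanged
  shifted <- m
  shifted[2, -1] <- shifted[2, -1] + 5
  calls2 <- call_ts_degs(median_profile(shifted, c(4, 8, 12)))
  expect_equal(calls2$is_deg, calls$is_deg)
})

test_that("the permutation fold-change cutoff is calibrated", {
  const <- tibble::tibble(gene_id = paste0("g", 1:5),
                          d4_r1 = 1:5, d8_r1 = 1:5, d12_r1 = 1:5)
  expect_equal(permutation_fc_cutoff(const, c(4, 8, 12), n_perm = 10), 1)

  sim <- simulate_timeseries(n_genes = 200, frac_up = 0, frac_down = 0,
                             noise_sd = 0.5, seed = 5)
  c1 <- permutation_fc_cutoff(sim$expr, sim$time, n_perm = 30, seed = 9)
  expect_identical(c1,
                   permutation_fc_cutoff(sim$expr, sim$time, n_perm = 30,
                                         seed = 9))
  # agrees with a 10x larger permutation run within Monte-Carlo tolerance
  c10 <- permutation_fc_cutoff(sim$expr, sim$time, n_perm = 300, seed = 10)
  expect_lt(abs(log2(c1) - log2(c10)), 0.05)
  expect_error(permutation_fc_cutoff(sim$expr, sim$time, n_perm = 0),
               "at least 1")
})

test_that("trajectory classification recovers planted classes", {
  sim <- simulate_timeseries(n_genes = 500, frac_up = 0.2, frac_down = 0.2,
                             max_change = 3, noise_sd = 0.2, seed = 12)
  fit <- deg_timeseries(sim$expr, sim$time, k = 40, seed = 12)
  tab <- tidy(fit)
  truth <- sim$truth

  expected <- dplyr::case_when(truth$direction == 1 ~ "up",
                               truth$direction == -1 ~ "down",
                               TRUE ~ NA_character_)
  got <- as.character(tab$class)
  # DEG recall and class agreement on planted genes; flat genes not called
  expect_gte(mean(tab$is_deg[truth$is_deg]), 0.95)
  expect_gte(mean(got[truth$is_deg] == expected[truth$is_deg], na.rm = TRUE),
             0.95)
  expect_lte(mean(tab$is_deg[!truth$is_deg]), 0.05)

  # determinism
  fit2 <- deg_timeseries(sim$expr, sim$time, k = 40, seed = 12)
  expect_identical(tidy(fit2), tab)
})

test_that("classification handles single-trend and degenerate inputs", {
  sim <- simulate_timeseries(n_genes = 60, frac_up = 1, frac_down = 0,
                             max_change = 3, noise_sd = 0.1, seed = 13)
  prof <- median_profile(sim$expr, sim$time)
  calls <- call_ts_degs(prof)
  out <- suppressWarnings(
    cluster_and_classify(prof, calls$is_deg, k = 2, seed = 1))
  expect_true(all(out$class[out$is_deg] == "up"))

  # scaling a noiseless profile does not change its assignment
  s0 <- simulate_timeseries(n_genes = 40, frac_up = 0.5, frac_down = 0.5,
                            max_change = 3, noise_sd = 0, seed = 14)
  p0 <- median_profile(s0$expr, s0$time)
  c0 <- call_ts_degs(p0)
  base <- cluster_and_classify(p0, c0$is_deg, k = 2, seed = 2)
  scaled_expr <- s0$expr
  scaled_expr[, -1] <- scaled_expr[, -1] * 2.5
  ps <- median_profile(scaled_expr, s0$time)
  cs <- cluster_and_classify(ps, call_ts_degs(ps)$is_deg, k = 2, seed = 2)
  expect_equal(as.character(cs$class), as.character(base$class))

  # constant delta profile goes to others, with a warning
  flat_deg <- tibble::tibble(gene_id = c("g1", "g2"),
                             d4_r1 = c(0, 0), d8_r1 = c(2, 0),
                             d12_r1 = c(3, 0))
  pf <- median_profile(flat_deg, c(4, 8, 12))
  expect_warning(
    outf <- cluster_and_classify(pf, c(TRUE, TRUE), k = 1, seed = 1),
    "constant")
  expect_equal(as.character(outf$class), c("up", "others"))

  # k reduced when fewer DEG profiles than clusters
  expect_warning(cluster_and_classify(pf, c(TRUE, FALSE), k = 5, seed = 1),
                 "reducing k")
})
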