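test_that("quantile normalization matches the brute-force oracle", {
  # hand-derivable case: both columns become the rank-wise column means
  out <- quantile_normalize(tiny_expr())
  expect_equal(out$s1, c(2.5, 3.5, 4.5))
  expect_equal(out$s2, c(2.5, 3.5, 4.5))

  withr::with_seed(33, {
    for (i in 1:5) {
      m <- matrix(rnorm(200), 50, 4,
                  dimnames = list(sprintf("p%02d", 1:50), paste0("s", 1:4)))
      got <- as.matrix(quantile_normalize(m)[, -1])
      expect_equal(got, qn_oracle(m), ignore_attr = TRUE, tolerance = 1e-12)
      # sorted columns pairwise identical
      sorted <- apply(got, 2, sort)
      expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
      # rank order preserved within each column
      expect_equal(apply(got, 2, rank), apply(m, 2, rank),
                   ignore_attr = TRUE)
      # idempotence
      again <- as.matrix(quantile_normalize(got)[, -1])
      expect_equal(again, got, ignore_attr = TRUE, tolerance = 1e-12)
    }
  })
})

test_that("quantile normalization handles degenerate shapes and bad input", {
  one <- tibble::tibble(probe_id = c("a", "b"), s1 = c(2, 1))
  expect_equal(quantile_normalize(one)$s1, c(2, 1))

  ident <- tibble::tibble(probe_id = c("a", "b"), s1 = c(1, 5), s2 = c(1, 5))
  out <- quantile_normalize(ident)
  expect_equal(out$s1, c(1, 5))
  expect_equal(out$s2, c(1, 5))

  bad <- tibble::tibble(probe_id = "a", s1 = NA_real_)
  expect_error(quantile_normalize(bad), "non-finite")
})

test_that("mixture cutoff sits at the density crossing between the means", {
  # symmetric planted mixture: the crossing is the midpoint
  withr::with_seed(1, x <- c(rnorm(10000, 2, 1), rnorm(10000, 10, 1)))
  fit <- fit_presence(matrix(x, ncol = 1, dimnames = list(NULL, "s1")))
  expect_false(fit$models$fallback)
  expect_lt(abs(fit$models$cutoff - 6), 0.15)

  # asymmetric planted mixture vs the numerically solved analytic root
  withr::with_seed(2, {
    n <- 20000
    comp <- rbinom(n, 1, 0.7)
    y <- ifelse(comp == 1, rnorm(n, 9, 1), rnorm(n, 4, 1))
  })
  fity <- fit_presence(matrix(y, ncol = 1, dimnames = list(NULL, "s1")))
  m <- fity$models
  root <- crossing_oracle(m$w1, m$mu1, m$sd1, m$w2, m$mu2, m$sd2)
  expect_lt(abs(m$cutoff - root), 1e-6)      # same fit, independent root finder
  truth_root <- crossing_oracle(0.3, 4, 1, 0.7, 9, 1)
  expect_lt(abs(m$cutoff - truth_root), 0.1)

  # parameter recovery within 3 standard errors at n = 20,000
  expect_lt(abs(m$mu1 - 4), 3 * 1 / sqrt(0.3 * n))
  expect_lt(abs(m$mu2 - 9), 3 * 1 / sqrt(0.7 * n))
  expect_lt(abs(m$w2 - 0.7), 3 * sqrt(0.3 * 0.7 / n))
  # cutoff lies between the fitted means
  expect_true(m$mu1 <= m$cutoff && m$cutoff <= m$mu2)
})

test_that("mixture fit agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  withr::with_seed(8, x <- c(rnorm(6000, 3, 0.8), rnorm(14000, 9, 1.3)))
  fit <- fit_presence(matrix(x, ncol = 1, dimnames = list(NULL, "s1")))$models
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mu_ref <- sort(ref$parameters$mean)
  expect_lt(abs(fit$mu1 - mu_ref[1]), 0.05)
  expect_lt(abs(fit$mu2 - mu_ref[2]), 0.05)
})

test_that("degenerate intensity distributions are flagged, never silent", {
  withr::with_seed(3, uni <- rnorm(5000, 5, 1))
  expect_warning(
    fit <- fit_presence(matrix(uni, ncol = 1, dimnames = list(NULL, "s1"))),
    "midpoint")
  expect_true(fit$models$fallback)

  const <- matrix(rep(3, 100), ncol = 1, dimnames = list(NULL, "s1"))
  expect_error(fit_presence(const), "zero variance")
  expect_error(fit_presence(matrix(rnorm(5), ncol = 1,
                                   dimnames = list(NULL, "s1"))),
               "at least 10")
})

test_that("present calls recover planted absent/present labels", {
  sim <- simulate_two_group(n_probes = 2000, n_per_group = 3,
                            frac_absent = 0.3, absent_mean = 4,
                            absent_sd = 0.8, present_mean = 10,
                            present_sd = 1, frac_deg = 0, noise_sd = 0.2,
                            seed = 21)
  norm <- quantile_normalize(sim$expr)
  fit <- fit_presence(norm)
  mask <- call_present(norm, fit, groups = sim$metadata$group)
  agreement <- mean(mask$present == !sim$truth$is_absent)
  expect_gte(agreement, 0.99)
})

test_that("present-call aggregation rules behave as documented", {
  vals <- tibble::tibble(probe_id = c("a", "b", "c"),
                         s1 = c(10, 10, 1), s2 = c(10, 1, 1),
                         s3 = c(10, 10, 1), s4 = c(10, 10, 1))
  fit <- structure(list(models = tibble::tibble(
    sample = paste0("s", 1:4), w1 = 0.5, mu1 = 0, sd1 = 1,
    w2 = 0.5, mu2 = 10, sd2 = 1, cutoff = 5, fallback = FALSE,
    loglik = NA_real_, iterations = 0L)), class = "presence_fit")
  groups <- c("g1", "g1", "g2", "g2")

  expect_equal(call_present(vals, fit, groups)$present, c(TRUE, TRUE, FALSE))
  expect_equal(call_present(vals, fit, aggregate = "all")$present,
               c(TRUE, FALSE, FALSE))
  expect_equal(call_present(vals, fit, aggregate = "any")$present,
               c(TRUE, TRUE, FALSE))
  expect_equal(call_present(vals, fit, aggregate = 0.75)$present,
               c(TRUE, TRUE, FALSE))
  expect_error(call_present(vals[, 1:3], fit, groups), "do not match")
})
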