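test_that("pooled-variance t statistic matches the hand-computed value", {
  # means 2 and 5, pooled variance 1, se = sqrt(2/3)
  expect_equal(t_statistic(c(1, 2, 3), c(4, 5, 6)), -3.674, tolerance = 1e-3)
  expect_equal(t_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(t_statistic(c(4, 5, 6), c(1, 2, 3)),
               -t_statistic(c(1, 2, 3), c(4, 5, 6)))
  # zero pooled variance: signed infinity sentinel / exact zero
  expect_identical(t_statistic(c(1, 1), c(2, 2)), -Inf)
  expect_identical(t_statistic(c(2, 2), c(2, 2)), 0)
  expect_error(t_statistic(1, c(1, 2)), "at least 2")
})

test_that("log2 median ratio is the difference of group medians", {
  expect_equal(log2_median_ratio(c(3, 5, 7), c(1, 2, 3)), 3)
  expect_equal(log2_median_ratio(c(1, 2), c(1, 2)), 0)
  # translation equivariance
  withr::with_seed(4, {
    a <- rnorm(7); b <- rnorm(5)
    expect_equal(log2_median_ratio(a + 1.3, b),
                 log2_median_ratio(a, b) + 1.3)
  })
  expect_error(log2_median_ratio(numeric(0), 1), "at least 1")
})

test_that("Stouffer combination matches its closed form", {
  expect_equal(stouffer_combine(1, 1, 1, 1), 1)
  expect_equal(stouffer_combine(0.05, 0.05, 1, 1), 0.00557, tolerance = 1e-3)
  expect_equal(stouffer_combine(0.05, 0.05, 1, -1), 1)

  # analytic grid, recomputed step by step in the test
  grid <- expand.grid(p1 = c(1e-6, 0.001, 0.05, 0.3, 0.77, 1),
                      p2 = c(1e-5, 0.01, 0.32, 0.5, 1),
                      s1 = c(-1, 1), s2 = c(-1, 1))
  got <- stouffer_combine(grid$p1, grid$p2, grid$s1, grid$s2)
  z <- (qnorm(1 - grid$p1 / 2) * grid$s1 +
          qnorm(1 - grid$p2 / 2) * grid$s2) / sqrt(2)
  expect_equal(got, 2 * pnorm(-abs(z)), tolerance = 1e-10)
  expect_true(all(got > 0 & got <= 1))

  expect_error(stouffer_combine(0, 0.5, 1, 1), "\\(0, 1\\]")
  expect_error(stouffer_combine(0.5, 1.2, 1, 1), "\\(0, 1\\]")
})

test_that("three-criterion DEG call gates on presence, p and fold-change", {
  rec <- tibble::tibble(
    probe_id = c("a", "b", "c", "d", "e"),
    present = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    p_combined = c(0.01, 0.001, 0.01, 0.2, 0.01),
    lmr = c(1.0, 3.0, 0.58, 2.0, -1.0))
  out <- call_degs(rec)
  expect_equal(as.character(out$call), c("up", "none", "none", "none", "down"))
  expect_error(call_degs(rec, alpha = 0), "\\(0, 1\\)")
})

test_that("the two-group pipeline recovers planted effects with correct signs", {
  sim <- simulate_two_group(n_probes = 800, n_per_group = 5, frac_deg = 0.1,
                            effect_size = 3, noise_sd = 0.3, seed = 14)
  fit <- deg_two_group(sim$expr, sim$metadata, B = 100, seed = 14)
  tab <- tidy(fit)
  planted <- sim$truth$is_deg
  sens <- mean(tab$call[planted] != "none")
  expect_gte(sens, 0.9)
  hit <- planted & tab$call != "none"
  expect_equal(ifelse(tab$call[hit] == "up", 1L, -1L),
               sim$truth$direction[hit])
  g <- glance(fit)
  expect_equal(g$n_up + g$n_down, sum(tab$call != "none"))
  expect_equal(g$percent_deg, deg_fraction(g$n_up, g$n_down, g$n_probes))
})

test_that("the pipeline is deterministic and invariant to sample order", {
  sim <- simulate_two_group(n_probes = 200, n_per_group = 3, seed = 6)
  f1 <- deg_two_group(sim$expr, sim$metadata, B = 60, seed = 3)
  f2 <- deg_two_group(sim$expr, sim$metadata, B = 60, seed = 3)
  expect_identical(tidy(f1), tidy(f2))

  perm <- withr::with_seed(5, sample(ncol(sim$expr) - 1))
  shuffled <- sim$expr[, c(1, 1 + perm)]
  f3 <- deg_two_group(shuffled, sim$metadata, B = 60, seed = 3,
                      group_a = "low")
  expect_equal(tidy(f3), tidy(f1))

  expect_error(deg_two_group(sim$expr, sim$metadata[-c(1, 2), ]),
               "metadata")
})
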