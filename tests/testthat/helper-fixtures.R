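# Shared fixture builders for the test suite.

# Brute-force quantile normalization: sort each column, average across
# columns per rank, reassign by rank. Independent of the package path.
qn_oracle <- function(m) {
  ranks <- apply(m, 2L, rank, ties.method = "first")
  sorted <- apply(m, 2L, sort)
  ref <- rowMeans(sorted)
  out <- apply(ranks, 2L, function(r) ref[r])
  dimnames(out) <- dimnames(m)
  out
}

# Analytic crossing of two weighted Gaussian densities, found numerically and
# independently of the package's quadratic solution.
crossing_oracle <- function(w1, mu1, s1, w2, mu2, s2) {
  f <- function(x) w1 * dnorm(x, mu1, s1) - w2 * dnorm(x, mu2, s2)
  uniroot(f, c(mu1, mu2), tol = 1e-10)$root
}

# A tiny expression tibble with fixed values.
tiny_expr <- function() {
  tibble::tibble(probe_id = c("a", "b", "c"),
                 s1 = c(1, 2, 3), s2 = c(4, 5, 6))
}
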