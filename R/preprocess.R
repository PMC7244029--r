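#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution: the
#' values of each column are replaced, at their original rank positions, by
#' the row-wise mean of the per-column sorted values. Tied values within a
#' column receive the mean of the reference values at their tied ranks, so the
#' operation is deterministic. Normalizing an already-normalized matrix is a
#' no-op, and a single-column matrix is returned unchanged.
#'
#' @param data Probes-x-samples table: a data frame whose first column holds
#'   probe ids, or a numeric matrix with rownames.
#' @return A tibble of the same shape with normalized values (first column
#'   `probe_id`).
#' @examples
#' m <- tibble::tibble(probe_id = c("a", "b", "c"),
#'                     s1 = c(1, 2, 3), s2 = c(4, 5, 6))
#' quantile_normalize(m)
#' @export
quantile_normalize <- function(data) {
  x <- as_expr_matrix(data)
  check_finite(x)
  if (ncol(x) < 1L) abort("need at least one sample.")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  matrix_to_tibble(out)
}

# Crossing point of two weighted Gaussian densities in (mu1, mu2): the root of
# w1 N(x; mu1, s1) = w2 N(x; mu2, s2), a quadratic in x on the log scale.
# Returns NA when no root falls strictly between the means.
mixture_crossing <- function(w, mu, sg) {
  a <- 1 / (2 * sg[2]^2) - 1 / (2 * sg[1]^2)
  b <- mu[1] / sg[1]^2 - mu[2] / sg[2]^2
  cc <- log(w[1] / sg[1]) - log(w[2] / sg[2]) -
    mu[1]^2 / (2 * sg[1]^2) + mu[2]^2 / (2 * sg[2]^2)
  if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) return(NA_real_)
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(NA_real_)
    roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
  }
  inside <- roots[roots > mu[1] & roots < mu[2]]
  if (length(inside) == 0L) NA_real_ else inside[which.min(abs(inside - mean(mu)))]
}

# Deterministic two-component Gaussian EM for one sample's intensities.
# Initialization: split at the median, moment-match each half; convergence on
# relative log-likelihood change < tol or max_iter iterations.
fit_mixture_em <- function(x, max_iter = 500L, tol = 1e-8) {
  if (length(x) < 10L) abort("need at least 10 values to fit the mixture.")
  s0 <- sd(x)
  if (!is.finite(s0) || s0 == 0) abort("intensities have zero variance; mixture fit is undefined.")

  m0 <- median(x)
  lo <- x[x <= m0]
  hi <- x[x > m0]
  mu <- c(mean(lo), mean(hi))
  sg <- pmax(c(sd(lo), sd(hi)), 1e-3 * s0)
  sg[is.na(sg)] <- 1e-3 * s0
  w <- c(length(lo), length(hi)) / length(x)

  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sg[1])
    d2 <- w[2] * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    r <- d1 / tot
    ll <- sum(log(tot))

    n1 <- sum(r)
    n2 <- length(x) - n1
    if (n1 < 2 || n2 < 2) {
      abort(sprintf(
        "mixture fit degenerated: component weights %.3g/%.3g after %d iterations.",
        n1 / length(x), n2 / length(x), it))
    }
    w <- c(n1, n2) / length(x)
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    sg <- sqrt(c(sum(r * (x - mu[1])^2) / n1, sum((1 - r) * (x - mu[2])^2) / n2))
    if (any(sg < 1e-6 * s0)) {
      abort("mixture fit degenerated: a component collapsed to a point mass.")
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) break
    ll_old <- ll
  }

  ord <- order(mu)
  list(w = w[ord], mu = mu[ord], sd = sg[ord], loglik = ll, iterations = it)
}

#' Fit per-sample presence models (two-component Gaussian mixtures)
#'
#' For each sample, fits a two-component Gaussian mixture to the distribution
#' of normalized log2 intensities by deterministic EM and locates the cutoff
#' where the two weighted component densities meet, between the two component
#' means. Probes brighter than this cutoff are considered expressed above
#' background ("present"). The low-mean component models background/absent
#' probes, the high-mean component expressed probes.
#'
#' When the fitted components are too close to represent distinct background
#' and signal populations (mean separation below `min_separation` times the
#' larger component sd -- two equal-sd Gaussians only produce a bimodal
#' density once their means are more than two sds apart), or when no density
#' crossing falls between the means, the cutoff falls back to the midpoint of
#' the two means and the sample is flagged (`fallback = TRUE`) with a
#' warning -- never silently.
#'
#' @param data Probes-x-samples table (data frame with id first column, or
#'   numeric matrix).
#' @param min_separation Minimum `(mu2 - mu1) / max(sd1, sd2)` for the fit to
#'   count as genuinely bimodal (default 2).
#' @return An object of class `presence_fit`; `tidy()` gives one row per
#'   sample with weights, means, sds, the cutoff and the fallback flag.
#' @examples
#' sim <- simulate_two_group(n_probes = 500, n_per_group = 2, seed = 1)
#' fit <- fit_presence(quantile_normalize(sim$expr))
#' tidy(fit)
#' @export
fit_presence <- function(data, min_separation = 2) {
  x <- as_expr_matrix(data)
  check_finite(x)
  fits <- purrr::map(seq_len(ncol(x)), function(j) {
    f <- fit_mixture_em(x[, j])
    cut <- mixture_crossing(f$w, f$mu, f$sd)
    sep_ok <- (f$mu[2] - f$mu[1]) >= min_separation * max(f$sd)
    fallback <- is.na(cut) || !sep_ok
    if (fallback) {
      warn(sprintf(
        "sample '%s': %s; using the midpoint of the component means as cutoff.",
        colnames(x)[j],
        if (is.na(cut)) "no density crossing between the component means"
        else "component means are not well separated (near-unimodal fit)"))
      cut <- mean(f$mu)
    }
    tibble(sample = colnames(x)[j],
           w1 = f$w[1], mu1 = f$mu[1], sd1 = f$sd[1],
           w2 = f$w[2], mu2 = f$mu[2], sd2 = f$sd[2],
           cutoff = cut, fallback = fallback,
           loglik = f$loglik, iterations = f$iterations)
  })
  structure(list(models = dplyr::bind_rows(fits)), class = "presence_fit")
}

#' @export
print.presence_fit <- function(x, ...) {
  cat("Per-sample two-Gaussian presence models\n")
  print(x$models, ...)
  invisible(x)
}

#' @rdname fit_presence
#' @param x A `presence_fit` object.
#' @param ... Unused.
#' @export
tidy.presence_fit <- function(x, ...) x$models

#' Call present probes against fitted presence models
#'
#' A probe is called present in a sample when its intensity strictly exceeds
#' that sample's mixture cutoff. Per-sample calls are aggregated to one
#' per-probe flag:
#' \describe{
#'   \item{`"group-all"`}{present in every sample of at least one group
#'     (default; a gene reliably detected in one condition is analyzable).
#'     Requires `groups`.}
#'   \item{`"all"`}{present in every sample.}
#'   \item{`"any"`}{present in at least one sample.}
#'   \item{a number in (0, 1]}{present in at least that fraction of samples.}
#' }
#'
#' @param data Probes-x-samples table, same samples as used for the fit.
#' @param fit A [fit_presence()] result.
#' @param groups Character vector of group labels, one per sample (needed for
#'   `aggregate = "group-all"`).
#' @param aggregate Aggregation rule; see Details.
#' @return A tibble with `probe_id`, one logical column per sample, and the
#'   aggregated logical column `present`.
#' @export
call_present <- function(data, fit, groups = NULL, aggregate = "group-all") {
  x <- as_expr_matrix(data)
  check_finite(x)
  if (!inherits(fit, "presence_fit")) abort("`fit` must be a presence_fit.")
  models <- fit$models
  if (!identical(colnames(x), models$sample)) {
    abort("samples in `data` do not match the samples the model was fitted to.")
  }
  calls <- sweep(x, 2L, models$cutoff, ">")

  if (is.numeric(aggregate)) {
    check_fraction(aggregate, "aggregate")
    present <- rowMeans(calls) >= aggregate
  } else if (identical(aggregate, "all")) {
    present <- rowSums(calls) == ncol(calls)
  } else if (identical(aggregate, "any")) {
    present <- rowSums(calls) > 0L
  } else if (identical(aggregate, "group-all")) {
    if (is.null(groups) || length(groups) != ncol(x)) {
      abort("`aggregate = \"group-all\"` needs one group label per sample.")
    }
    per_group <- vapply(unique(groups), function(g) {
      rowSums(calls[, groups == g, drop = FALSE]) == sum(groups == g)
    }, logical(nrow(calls)))
    present <- rowSums(per_group) > 0L
  } else {
    abort("`aggregate` must be \"group-all\", \"all\", \"any\" or a fraction.")
  }

  out <- matrix_to_tibble(calls)
  out$present <- unname(present)
  out
}

#' Plot fitted presence models over the intensity distributions
#'
#' Overlays each sample's intensity histogram with the two fitted Gaussian
#' component densities and the present/absent cutoff.
#'
#' @param object A `presence_fit`.
#' @param data The probes-x-samples table the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object, faceted by sample.
#' @export
autoplot.presence_fit <- function(object, data, ...) {
  x <- as_expr_matrix(data)
  long <- tidyr::pivot_longer(matrix_to_tibble(x), -"probe_id",
                              names_to = "sample", values_to = "intensity")
  models <- object$models
  grid <- tidyr::expand_grid(models,
                             intensity = seq(min(x), max(x), length.out = 200))
  grid <- dplyr::mutate(
    grid,
    component1 = .data$w1 * dnorm(.data$intensity, .data$mu1, .data$sd1),
    component2 = .data$w2 * dnorm(.data$intensity, .data$mu2, .data$sd2))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$intensity)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey80") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$component1),
                       colour = "#4477AA") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$component2),
                       colour = "#CC6677") +
    ggplot2::geom_vline(data = models,
                        ggplot2::aes(xintercept = .data$cutoff),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = "normalized log2 intensity", y = "density")
}
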