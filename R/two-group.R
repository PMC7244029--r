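#' Two-sample test statistics for the integrative DEG test
#'
#' `t_statistic()` is the classical pooled-variance (Student) two-sample t
#' statistic, signed positive when `a` has the larger mean. With zero pooled
#' variance it returns 0 for equal means and a signed infinity otherwise
#' (downstream empirical p-values treat infinities as maximally extreme).
#' `log2_median_ratio()` is the difference of group medians on the log2
#' scale, i.e. the log2 ratio of group medians on the linear scale -- a robust
#' effect-size statistic.
#'
#' @param a,b Numeric vectors of log2 expression values for the two groups.
#'   `t_statistic()` needs at least 2 values per group; `log2_median_ratio()`
#'   at least 1.
#' @return A single numeric value.
#' @examples
#' t_statistic(c(1, 2, 3), c(4, 5, 6))
#' log2_median_ratio(c(3, 5, 7), c(1, 2, 3))
#' @export
t_statistic <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("each group needs at least 2 values for the t statistic.")
  }
  as.numeric(row_t_pooled(matrix(a, nrow = 1), matrix(b, nrow = 1)))
}

#' @rdname t_statistic
#' @export
log2_median_ratio <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) {
    abort("each group needs at least 1 value for the log2 median ratio.")
  }
  median(a) - median(b)
}

# Group-size-preserving relabelings as index sets for group A. Exhaustive
# (each distinct relabeling once) when the space has at most B members,
# otherwise B uniform draws.
relabelings <- function(n, n_a, B) {
  n_distinct <- choose(n, n_a)
  if (n_distinct <= B) {
    list(idx = utils::combn(n, n_a), exhaustive = TRUE)
  } else {
    list(idx = replicate(B, sort(sample.int(n, n_a))), exhaustive = FALSE)
  }
}

#' Permutation empirical null distribution for a two-group statistic
#'
#' Recomputes the chosen statistic for every probe under `B` random
#' relabelings of the samples that preserve the group sizes, pools all
#' probe-by-permutation values into a single null sample, and smooths it with
#' a Gaussian kernel density estimate (Silverman bandwidth, 2048 grid points
#' spanning the null range plus four bandwidths on each side). When the number
#' of distinct relabelings is at most `B`, every relabeling is enumerated
#' exactly once instead (exhaustive mode).
#'
#' The null is pooled across probes -- one empirical distribution per
#' statistic per data set -- so moderate permutation counts suffice.
#'
#' @param data Probes-x-samples table.
#' @param groups Character vector of group labels (two levels), one per
#'   sample; the first label in order of appearance is "group A" so that the
#'   statistic's sign convention matches [deg_two_group()].
#' @param statistic `"t"` (pooled-variance Student t) or `"lmr"` (log2 median
#'   ratio).
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed for the relabelings.
#' @return An object of class `perm_null` holding the pooled draws, the KDE
#'   (`$kde`), the null center (median of the draws), the p-value floor, and
#'   bookkeeping (`B`, `exhaustive`, `seed`).
#' @export
permutation_null <- function(data, groups, statistic = c("t", "lmr"),
                             B = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  if (B < 1) abort("`B` must be at least 1.")
  x <- as_expr_matrix(data)
  check_finite(x)
  if (length(groups) != ncol(x)) abort("one group label per sample required.")
  lev <- unique(groups)
  if (length(lev) != 2L) abort("exactly two groups required.")
  n_a <- sum(groups == lev[1])
  if (n_a < 2L || sum(groups == lev[2]) < 2L) {
    abort("at least 2 samples per group required.")
  }

  stat_fun <- if (statistic == "t") {
    function(a, b) row_t_pooled(a, b)
  } else {
    function(a, b) row_medians(a) - row_medians(b)
  }

  rel <- withr::with_seed(seed, relabelings(ncol(x), n_a, B))
  draws <- apply(rel$idx, 2L, function(idx) {
    stat_fun(x[, idx, drop = FALSE], x[, -idx, drop = FALSE])
  })
  draws <- as.vector(draws)
  n_dropped <- sum(!is.finite(draws))
  draws <- draws[is.finite(draws)]
  if (length(draws) < 10L) abort("too few finite permutation draws for a null.")

  h <- bw.nrd0(draws)
  kde <- density(draws, bw = h, n = 2048,
                 from = min(draws) - 4 * h, to = max(draws) + 4 * h)

  structure(list(
    statistic = statistic,
    draws = draws,
    B = ncol(rel$idx),
    exhaustive = rel$exhaustive,
    seed = seed,
    bandwidth = h,
    kde = kde,
    center = median(draws),
    p_floor = 1 / length(draws),
    n_dropped = n_dropped
  ), class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf(
    "Permutation null for '%s': %d relabelings (%s), %d pooled draws, bw %.4g\n",
    x$statistic, x$B, if (x$exhaustive) "exhaustive" else "sampled",
    length(x$draws), x$bandwidth))
  invisible(x)
}

#' Two-tailed empirical p-values from a permutation null
#'
#' The p-value of an observed statistic is the two-tailed mass of the
#' smoothed null density beyond `center +/- |observed - center|`, where the
#' center is the null median, obtained by trapezoidal integration of the KDE
#' on its grid. P-values are clamped below at the null's floor (one over the
#' number of pooled draws) so downstream normal-quantile transforms stay
#' finite; non-finite observed statistics (the zero-variance sentinel) get
#' the floor.
#'
#' @param observed Numeric vector of observed statistics.
#' @param null A [permutation_null()] result.
#' @return Numeric vector of p-values in (0, 1].
#' @export
empirical_pvalue <- function(observed, null) {
  if (!inherits(null, "perm_null")) abort("`null` must be a perm_null.")
  gx <- null$kde$x
  gy <- null$kde$y
  cum <- c(0, cumsum(diff(gx) * (head(gy, -1) + tail(gy, -1)) / 2))
  total <- cum[length(cum)]
  lower_mass <- approxfun(gx, cum, yleft = 0, yright = total)

  d <- abs(observed - null$center)
  p <- (lower_mass(null$center - d) + (total - lower_mass(null$center + d))) / total
  p[!is.finite(observed)] <- 0
  pmin(pmax(p, null$p_floor), 1)
}

#' Combine two-tailed p-values with Stouffer's method
#'
#' Each two-tailed p-value is converted to a signed z score,
#' `z = qnorm(1 - p/2) * sign`, where the sign is that of the underlying
#' statistic; the combined score is `(z_t + z_lmr) / sqrt(2)` (equal weights)
#' and the result is its two-tailed normal p-value. Two equally significant
#' p-values with opposite signs cancel to a combined p of 1.
#'
#' @param p_t,p_lmr Two-tailed p-values in (0, 1].
#' @param sign_t,sign_lmr Signs of the corresponding statistics (interpreted
#'   via `sign()`; 0 gives a zero z score).
#' @return Numeric vector of combined two-tailed p-values in (0, 1].
#' @examples
#' stouffer_combine(0.05, 0.05, 1, 1)   # reinforcing evidence
#' stouffer_combine(0.05, 0.05, 1, -1)  # contradictory evidence
#' @export
stouffer_combine <- function(p_t, p_lmr, sign_t, sign_lmr) {
  for (p in list(p_t, p_lmr)) {
    if (any(!is.finite(p) | p <= 0 | p > 1)) {
      abort("p-values must lie in (0, 1].")
    }
  }
  z_t <- qnorm(1 - p_t / 2) * sign(sign_t)
  z_l <- qnorm(1 - p_lmr / 2) * sign(sign_lmr)
  z <- (z_t + z_l) / sqrt(2)
  2 * pnorm(-abs(z))
}

#' Apply the three-criterion DEG call
#'
#' A probe is called differentially expressed when (I) it is present, (II) its
#' combined p-value is below `alpha`, and (III) its absolute log2 fold-change
#' strictly exceeds `fc_cut` (default 0.58, i.e. 1.5-fold). The direction of
#' the call follows the sign of the fold-change. The log2 median ratio serves
#' as the fold-change statistic.
#'
#' @param records A data frame with columns `present` (logical),
#'   `p_combined`, and `lmr` (or the column named by `fc_col`).
#' @param alpha Combined p-value threshold (strict `<`).
#' @param fc_cut Absolute log2 fold-change threshold (strict `>`).
#' @param fc_col Name of the fold-change column.
#' @return The input tibble with a `call` factor column
#'   (`up`/`down`/`none`).
#' @export
call_degs <- function(records, alpha = 0.05, fc_cut = 0.58, fc_col = "lmr") {
  if (!all(c("present", "p_combined", fc_col) %in% names(records))) {
    abort(sprintf("`records` needs columns present, p_combined and %s.", fc_col))
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (fc_cut < 0) abort("`fc_cut` must be >= 0.")
  fc <- records[[fc_col]]
  hit <- records$present & records$p_combined < alpha & abs(fc) > fc_cut
  records$call <- factor(
    dplyr::case_when(hit & fc > 0 ~ "up", hit & fc < 0 ~ "down", TRUE ~ "none"),
    levels = c("up", "down", "none"))
  as_tibble(records)
}

#' Integrative two-group differential expression pipeline
#'
#' Runs the full two-group analysis: quantile normalization, per-sample
#' Gaussian-mixture present calling, pooled-variance t statistics and log2
#' median ratios (group A minus group B), permutation empirical nulls for both
#' statistics smoothed by Gaussian KDE, two-tailed empirical p-values,
#' Stouffer combination, and the three-criterion DEG call.
#'
#' @param data Probes-x-samples table (data frame with id first column or
#'   numeric matrix).
#' @param metadata Data frame with columns `sample` and `group` covering every
#'   sample column of `data`; exactly two groups, at least 2 samples each.
#' @param group_a Label of the group whose mean/median enters the statistics
#'   positively (default: first group in `metadata` order). For the
#'   physical-ability design this is the low-MV group, so positive calls are
#'   genes up in low-ability animals.
#' @param B Permutation count for the empirical nulls.
#' @param alpha Combined p-value threshold.
#' @param fc_cut Absolute log2 fold-change threshold (0.58 = 1.5-fold).
#' @param seed Integer seed (shared by both statistics' permutations).
#' @param normalize Quantile-normalize before testing (default TRUE).
#' @param aggregate Present-call aggregation rule, see [call_present()].
#' @return An object of class `deg_fit`. `tidy()` returns the per-probe table
#'   (`probe_id`, `t`, `lmr`, `p_t`, `p_lmr`, `p_combined`, `present`,
#'   `call`); `glance()` a one-row summary with `n_up`, `n_down` and
#'   `percent_deg`; `autoplot()` a volcano plot.
#' @examples
#' sim <- simulate_two_group(n_probes = 300, n_per_group = 4,
#'                           effect_size = 3, seed = 2)
#' fit <- deg_two_group(sim$expr, sim$metadata, B = 50, seed = 2)
#' glance(fit)
#' @export
deg_two_group <- function(data, metadata, group_a = NULL,
                          B = 1000, alpha = 0.05, fc_cut = 0.58, seed = 1,
                          normalize = TRUE, aggregate = "group-all") {
  x <- as_expr_matrix(data)
  check_finite(x)
  if (!all(c("sample", "group") %in% names(metadata))) {
    abort("`metadata` needs columns `sample` and `group`.")
  }
  meta <- metadata[match(colnames(x), metadata$sample), ]
  if (any(is.na(meta$sample))) abort("every sample column needs metadata.")
  groups <- as.character(meta$group)
  lev <- unique(groups)
  if (length(lev) != 2L) abort("exactly two groups required.")
  group_a <- group_a %||% lev[1]
  if (!group_a %in% lev) abort("`group_a` is not a group in `metadata`.")
  group_b <- setdiff(lev, group_a)
  if (sum(groups == group_a) < 2L || sum(groups == group_b) < 2L) {
    abort("at least 2 samples per group required.")
  }

  norm <- if (normalize) as_expr_matrix(quantile_normalize(x)) else x
  presence <- fit_presence(norm)
  mask <- call_present(norm, presence, groups = groups, aggregate = aggregate)

  a <- norm[, groups == group_a, drop = FALSE]
  b <- norm[, groups == group_b, drop = FALSE]
  t_obs <- row_t_pooled(a, b)
  lmr_obs <- row_medians(a) - row_medians(b)

  ord <- c(which(groups == group_a), which(groups == group_b))
  null_groups <- groups[ord]
  null_t <- permutation_null(norm[, ord, drop = FALSE], null_groups,
                             statistic = "t", B = B, seed = seed)
  null_lmr <- permutation_null(norm[, ord, drop = FALSE], null_groups,
                               statistic = "lmr", B = B, seed = seed)

  records <- tibble(
    probe_id = rownames(norm),
    t = t_obs,
    lmr = lmr_obs,
    p_t = empirical_pvalue(t_obs, null_t),
    p_lmr = empirical_pvalue(lmr_obs, null_lmr),
    present = mask$present
  )
  records$p_combined <- stouffer_combine(records$p_t, records$p_lmr,
                                         records$t, records$lmr)
  records <- call_degs(records, alpha = alpha, fc_cut = fc_cut)

  structure(list(
    table = records,
    presence = presence,
    nulls = list(t = null_t, lmr = null_lmr),
    groups = c(a = group_a, b = group_b),
    config = list(B = B, alpha = alpha, fc_cut = fc_cut, seed = seed,
                  normalize = normalize, aggregate = aggregate)
  ), class = "deg_fit")
}

#' @export
print.deg_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Integrative two-group DEG fit (%s vs %s): %d probes, %d up, %d down (%.1f%% DEG)\n",
    x$groups["a"], x$groups["b"], g$n_probes, g$n_up, g$n_down, g$percent_deg))
  invisible(x)
}

#' @rdname deg_two_group
#' @param x,object A `deg_fit` object.
#' @param ... Unused.
#' @export
tidy.deg_fit <- function(x, ...) x$table

#' @rdname deg_two_group
#' @export
glance.deg_fit <- function(x, ...) {
  tab <- x$table
  n_up <- sum(tab$call == "up")
  n_down <- sum(tab$call == "down")
  tibble(
    n_probes = nrow(tab),
    n_present = sum(tab$present),
    n_up = n_up,
    n_down = n_down,
    percent_deg = deg_fraction(n_up, n_down, nrow(tab)),
    B = x$config$B,
    alpha = x$config$alpha,
    fc_cut = x$config$fc_cut,
    seed = x$config$seed
  )
}

#' @rdname deg_two_group
#' @export
autoplot.deg_fit <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$lmr,
                                    y = -log10(.data$p_combined),
                                    colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$config$fc_cut,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(object$config$alpha),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(up = "#CC6677", down = "#4477AA",
                                            none = "grey70")) +
    ggplot2::labs(x = "log2 median ratio", y = "-log10 combined p")
}
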