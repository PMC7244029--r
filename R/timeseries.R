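#' Median expression profiles over a time course
#'
#' Collapses replicate measurements to a per-gene median profile: the median
#' log2 ratio at each time point, the difference of every time point from the
#' baseline day (day 4 of adulthood by default, i.e. the earliest time
#' point), and the maximum absolute change from baseline.
#'
#' @param data Genes-x-observations table (data frame with id first column or
#'   numeric matrix), one column per (time point, replicate).
#' @param time Numeric vector assigning each value column to its day.
#' @param baseline Baseline day; defaults to the earliest time point. Must be
#'   one of `time`.
#' @return An object of class `ts_profile` with the per-gene median profile
#'   matrix (`$profile`, genes x time points), the baseline-referenced deltas
#'   (`$delta`, zero in the baseline column), `$max_abs_change`, and the time
#'   grid. `tidy()` returns a long tibble of deltas.
#' @examples
#' sim <- simulate_timeseries(n_genes = 20, seed = 5)
#' prof <- median_profile(sim$expr, sim$time)
#' head(prof$max_abs_change)
#' @export
median_profile <- function(data, time, baseline = NULL) {
  x <- as_expr_matrix(data, what = "time-series matrix")
  check_finite(x, "time-series matrix")
  if (length(time) != ncol(x)) abort("one time label per value column required.")
  tp <- sort(unique(time))
  if (length(tp) < 2L) abort("need at least 2 distinct time points.")
  baseline <- baseline %||% tp[1]
  if (!baseline %in% tp) abort("`baseline` is not one of the time points.")

  profile <- matrix(
    vapply(tp, function(d) row_medians(x[, time == d, drop = FALSE]),
           numeric(nrow(x))),
    nrow = nrow(x), ncol = length(tp),
    dimnames = list(rownames(x), paste0("d", tp)))

  delta <- profile - profile[, match(baseline, tp)]
  structure(list(
    profile = profile,
    delta = delta,
    time = tp,
    baseline = baseline,
    max_abs_change = unname(apply(abs(delta), 1L, max))
  ), class = "ts_profile")
}

#' @rdname median_profile
#' @param x A `ts_profile` object.
#' @param ... Unused.
#' @export
tidy.ts_profile <- function(x, ...) {
  out <- matrix_to_tibble(x$delta, id_col = "gene_id")
  out <- tidyr::pivot_longer(out, -"gene_id", names_to = "day",
                             values_to = "delta")
  out$day <- as.numeric(sub("^d", "", out$day))
  out
}

#' Call time-series DEGs by maximum fold-change
#'
#' A gene is differentially expressed over the time course when its maximum
#' absolute change from baseline strictly exceeds the fold-change cutoff: on
#' the stored log2 ratios, `max_abs_change > log2(fc_cutoff)`. The default
#' linear cutoff of 2.5 corresponds to the 95th percentile of the empirical
#' fold-change distribution obtained by random permutations (see
#' [permutation_fc_cutoff()]).
#'
#' @param profiles A [median_profile()] result.
#' @param fc_cutoff Linear fold-change cutoff (> 1).
#' @return A tibble with `gene_id`, `max_abs_change` (log2 units) and
#'   `is_deg`.
#' @export
call_ts_degs <- function(profiles, fc_cutoff = 2.5) {
  if (!inherits(profiles, "ts_profile")) abort("`profiles` must be a ts_profile.")
  if (fc_cutoff <= 1) abort("`fc_cutoff` must exceed 1 (a linear fold-change).")
  tibble(
    gene_id = rownames(profiles$delta),
    max_abs_change = profiles$max_abs_change,
    is_deg = profiles$max_abs_change > log2(fc_cutoff)
  )
}

#' Permutation-calibrated fold-change cutoff for a time course
#'
#' Estimates the fold-change a flat gene can reach by chance: for each
#' permutation the observations of every gene are shuffled across the time
#' course independently (destroying any temporal trend while preserving each
#' gene's marginal distribution), the median profile and maximum absolute
#' change from baseline are recomputed, and all gene-by-permutation maxima
#' are pooled. The cutoff is the chosen percentile of that pooled empirical
#' distribution, returned on the linear fold-change scale.
#'
#' @inheritParams median_profile
#' @param n_perm Number of permutations.
#' @param percentile Percentile of the pooled null maxima (default 95).
#' @param seed Integer seed.
#' @return A single linear fold-change cutoff (`2^` of the log2 percentile).
#' @export
permutation_fc_cutoff <- function(data, time, baseline = NULL,
                                  n_perm = 100, percentile = 95, seed = 1) {
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  x <- as_expr_matrix(data, what = "time-series matrix")
  check_finite(x, "time-series matrix")
  if (length(time) != ncol(x)) abort("one time label per value column required.")
  if (length(unique(time)) < 3L) abort("need at least 3 time points.")

  withr::with_seed(seed, {
    pooled <- unlist(lapply(seq_len(n_perm), function(i) {
      xp <- shuffle_within_rows(x)
      median_profile(xp, time, baseline)$max_abs_change
    }), use.names = FALSE)
    2^as.numeric(quantile(pooled, percentile / 100))
  })
}

#' Cluster DEG trajectories and classify them as up, down or others
#'
#' Groups the baseline-referenced delta profiles of the time-series DEGs by
#' k-means with correlation distance (k = 40 by default): each profile is
#' standardized across time points so that Euclidean k-means on the
#' standardized rows orders pairs exactly as 1 - Pearson correlation. The k
#' centroid profiles are then clustered hierarchically (complete linkage,
#' Euclidean distance), the tree is cut into three groups, and each group is
#' labeled `up` or `down` by the sign of its member genes' mean end-minus-
#' baseline change, with a dead zone: groups whose mean absolute end change
#' is below `dead_zone` log2 units are labeled `others`. Constant delta
#' profiles (undefined correlation) are assigned to `others` without entering
#' k-means.
#'
#' @param profiles A [median_profile()] result restricted by the caller, or
#'   full; only rows flagged in `is_deg` are clustered.
#' @param is_deg Logical vector (one per gene) of DEG flags, e.g. from
#'   [call_ts_degs()].
#' @param k Number of k-means clusters (reduced with a warning when fewer DEG
#'   profiles are available).
#' @param dead_zone Log2 dead zone for the up/down labeling of the three
#'   trajectory groups.
#' @param seed Integer seed for the k-means restarts.
#' @return A tibble with `gene_id`, `is_deg`, `cluster_id` (NA for non-DEGs)
#'   and `class` (`up`/`down`/`others`, NA for non-DEGs), carrying the k-means
#'   centroids as attribute `"centroids"`.
#' @export
cluster_and_classify <- function(profiles, is_deg, k = 40, dead_zone = 0.1,
                                 seed = 1) {
  if (!inherits(profiles, "ts_profile")) abort("`profiles` must be a ts_profile.")
  delta <- profiles$delta
  if (length(is_deg) != nrow(delta)) abort("one `is_deg` flag per gene required.")

  genes <- rownames(delta)
  out <- tibble(gene_id = genes, is_deg = is_deg,
                cluster_id = NA_integer_,
                class = factor(NA, levels = c("up", "down", "others")))
  deg_rows <- which(is_deg)
  if (length(deg_rows) == 0L) return(out)

  d <- delta[deg_rows, , drop = FALSE]
  rs <- apply(d, 1L, sd)
  constant <- rs == 0
  if (any(constant)) {
    warn(sprintf("%d constant delta profiles assigned to 'others'.",
                 sum(constant)))
    out$class[deg_rows[constant]] <- "others"
  }
  active <- deg_rows[!constant]
  if (length(active) == 0L) return(out)

  z <- (d[!constant, , drop = FALSE] - rowMeans(d[!constant, , drop = FALSE])) /
    rs[!constant]
  k_eff <- k
  if (nrow(z) < k_eff) {
    warn(sprintf("only %d clusterable DEG profiles; reducing k from %d.",
                 nrow(z), k))
    k_eff <- nrow(z)
  }

  km <- withr::with_seed(seed, kmeans(z, centers = k_eff, nstart = 10,
                                      iter.max = 100))
  out$cluster_id[active] <- km$cluster

  n_classes <- min(3L, k_eff)
  tree_group <- if (k_eff == 1L) {
    1L
  } else {
    cutree(hclust(dist(km$centers), method = "complete"), k = n_classes)
  }
  end_col <- ncol(delta)
  gene_group <- tree_group[km$cluster]
  class_of <- vapply(seq_len(n_classes), function(g) {
    m <- mean(delta[active[gene_group == g], end_col])
    if (abs(m) < dead_zone) "others" else if (m > 0) "up" else "down"
  }, character(1))
  out$class[active] <- class_of[gene_group]

  attr(out, "centroids") <- km$centers
  out
}

#' Time-series differential expression pipeline
#'
#' Runs the full aging time-course analysis: per-gene median profiles
#' referenced to the baseline day, DEG calls by maximum absolute fold-change
#' (fixed 2.5 by default, or recomputed from the data as the 95th percentile
#' of a permutation null), and k-means + hierarchical classification of the
#' DEG trajectories into `up`, `down` and `others`.
#'
#' @inheritParams median_profile
#' @param fc_cutoff Linear fold-change cutoff for DEG calls.
#' @param recompute_cutoff Recompute the cutoff from the data with
#'   [permutation_fc_cutoff()] instead of using `fc_cutoff`.
#' @param n_perm,percentile Permutation settings when recomputing the cutoff.
#' @param k Number of k-means clusters.
#' @param dead_zone Log2 dead zone for up/down labeling.
#' @param seed Integer seed.
#' @return An object of class `ts_deg_fit`; `tidy()` returns the per-gene
#'   call table, `glance()` the counts and cutoff, `autoplot()` the classified
#'   mean trajectories.
#' @examples
#' sim <- simulate_timeseries(n_genes = 100, frac_up = 0.2, frac_down = 0.2,
#'                            seed = 4)
#' fit <- deg_timeseries(sim$expr, sim$time, k = 8, seed = 4)
#' glance(fit)
#' @export
deg_timeseries <- function(data, time, baseline = NULL,
                           fc_cutoff = 2.5, recompute_cutoff = FALSE,
                           n_perm = 100, percentile = 95,
                           k = 40, dead_zone = 0.1, seed = 1) {
  profiles <- median_profile(data, time, baseline)
  cutoff <- if (recompute_cutoff) {
    permutation_fc_cutoff(data, time, baseline, n_perm = n_perm,
                          percentile = percentile, seed = seed)
  } else {
    fc_cutoff
  }
  calls <- call_ts_degs(profiles, fc_cutoff = cutoff)
  classes <- cluster_and_classify(profiles, calls$is_deg, k = k,
                                  dead_zone = dead_zone, seed = seed)
  table <- dplyr::left_join(calls,
                            dplyr::select(classes, "gene_id", "cluster_id",
                                          "class"),
                            by = "gene_id")
  structure(list(
    table = table,
    profiles = profiles,
    centroids = attr(classes, "centroids"),
    config = list(fc_cutoff = cutoff, recomputed = recompute_cutoff,
                  k = k, dead_zone = dead_zone, seed = seed,
                  baseline = profiles$baseline)
  ), class = "ts_deg_fit")
}

#' @export
print.ts_deg_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Time-series DEG fit: %d genes, %d DEGs (fold-change cutoff %.3g): %d up, %d down, %d others\n",
    g$n_genes, g$n_deg, g$fc_cutoff, g$n_up, g$n_down, g$n_others))
  invisible(x)
}

#' @rdname deg_timeseries
#' @param x,object A `ts_deg_fit` object.
#' @param ... Unused.
#' @export
tidy.ts_deg_fit <- function(x, ...) x$table

#' @rdname deg_timeseries
#' @export
glance.ts_deg_fit <- function(x, ...) {
  tab <- x$table
  tibble(
    n_genes = nrow(tab),
    n_deg = sum(tab$is_deg),
    n_up = sum(tab$class == "up", na.rm = TRUE),
    n_down = sum(tab$class == "down", na.rm = TRUE),
    n_others = sum(tab$class == "others", na.rm = TRUE),
    fc_cutoff = x$config$fc_cutoff,
    k = x$config$k,
    seed = x$config$seed
  )
}

#' @rdname deg_timeseries
#' @export
autoplot.ts_deg_fit <- function(object, ...) {
  deltas <- tidy(object$profiles)
  deltas <- dplyr::left_join(deltas,
                             dplyr::select(object$table, "gene_id", "class"),
                             by = "gene_id")
  deltas <- dplyr::filter(deltas, !is.na(.data$class))
  ggplot2::ggplot(deltas, ggplot2::aes(x = .data$day, y = .data$delta,
                                       group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.2, colour = "grey60") +
    ggplot2::stat_summary(ggplot2::aes(group = .data$class),
                          fun = mean, geom = "line", colour = "#CC6677",
                          linewidth = 1) +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = "day of adulthood",
                  y = "log2 change from baseline")
}
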