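#' Simulate a two-group expression matrix with planted differential expression
#'
#' Generates a log2-intensity matrix (probes x samples) emulating a two-colour
#' microarray experiment in which worms of the same chronological age were
#' split into low and high physical-ability groups by maximum velocity. A
#' fraction of probes is "absent" (background-level intensity drawn from a
#' low-mean Gaussian in every sample); the remainder is "present" (drawn from
#' a high-mean Gaussian), and a fraction of the present probes carries a
#' planted mean shift of `effect_size` log2 units in the `"low"` group, with
#' the sign of the shift randomized per probe.
#'
#' Each probe receives one baseline intensity drawn from its component, shared
#' by all samples, plus independent per-observation Gaussian noise; with
#' `noise_sd = 0` the realized group difference of a planted probe equals its
#' planted effect exactly.
#'
#' @param n_probes Number of probes.
#' @param n_per_group Samples per group (at least 2).
#' @param frac_absent Fraction of probes drawn from the absent (background)
#'   component.
#' @param absent_mean,absent_sd,present_mean,present_sd Parameters (log2
#'   intensity units) of the absent and present components.
#' @param frac_deg Fraction of *present* probes carrying a planted group
#'   effect.
#' @param effect_size Planted mean shift in log2 units, applied to the low
#'   group with randomized sign.
#' @param noise_sd Per-observation Gaussian noise sd in log2 units.
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return A list with components
#'   \describe{
#'     \item{expr}{tibble, first column `probe_id`, one column per sample.}
#'     \item{metadata}{tibble with `sample`, `group` (`"low"`/`"high"`) and a
#'       simulated maximum velocity `mv` (mm/sec) consistent with the group.}
#'     \item{truth}{tibble with `probe_id`, `is_absent`, `is_deg`,
#'       `direction` (+1/-1/0) and planted `effect`.}
#'   }
#' @examples
#' sim <- simulate_two_group(n_probes = 200, n_per_group = 3, seed = 7)
#' head(sim$truth)
#' @export
simulate_two_group <- function(n_probes = 2000,
                               n_per_group = 5,
                               frac_absent = 0.3,
                               absent_mean = 4, absent_sd = 0.8,
                               present_mean = 10, present_sd = 1.2,
                               frac_deg = 0.1,
                               effect_size = 2,
                               noise_sd = 0.3,
                               seed = 1) {
  check_fraction(frac_absent, "frac_absent")
  check_fraction(frac_deg, "frac_deg")
  check_positive(absent_sd, "absent_sd")
  check_positive(present_sd, "present_sd")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (n_per_group < 2L) abort("`n_per_group` must be at least 2.")
  if (n_probes < 1L) abort("`n_probes` must be at least 1.")

  withr::with_seed(seed, {
    probe_id <- sprintf("g%05d", seq_len(n_probes))
    n_absent <- round(frac_absent * n_probes)
    is_absent <- rep(FALSE, n_probes)
    is_absent[sample.int(n_probes, n_absent)] <- TRUE

    baseline <- numeric(n_probes)
    baseline[is_absent] <- rnorm(n_absent, absent_mean, absent_sd)
    baseline[!is_absent] <- rnorm(n_probes - n_absent, present_mean, present_sd)

    present_idx <- which(!is_absent)
    n_deg <- round(frac_deg * length(present_idx))
    deg_idx <- sort(sample(present_idx, n_deg))
    direction <- integer(n_probes)
    direction[deg_idx] <- sample(c(-1L, 1L), n_deg, replace = TRUE)
    effect <- direction * effect_size

    samples <- c(sprintf("low_%d", seq_len(n_per_group)),
                 sprintf("high_%d", seq_len(n_per_group)))
    group <- rep(c("low", "high"), each = n_per_group)

    mu <- outer(baseline, rep(1, 2 * n_per_group)) +
      outer(effect, as.numeric(group == "low"))
    x <- mu + matrix(rnorm(n_probes * 2 * n_per_group, 0, noise_sd),
                     n_probes, 2 * n_per_group)
    dimnames(x) <- list(probe_id, samples)

    mv <- ifelse(group == "low",
                 runif(length(group), 0.05, 0.21),
                 runif(length(group), 0.23, 0.45))

    list(
      expr = matrix_to_tibble(x),
      metadata = tibble(sample = samples, group = group, mv = mv),
      truth = tibble(probe_id = probe_id,
                     is_absent = is_absent,
                     is_deg = direction != 0L,
                     direction = direction,
                     effect = effect)
    )
  })
}

#' Simulate an aging time-series log2-ratio matrix with planted trajectories
#'
#' Emulates a time-course of bulk expression log2 ratios over adult life
#' (default day 4 to day 24 of adulthood in 4-day steps). Planted "up" genes
#' rise linearly from their baseline value to baseline + `max_change` at the
#' final time point; "down" genes mirror this; all other genes are flat.
#' Independent Gaussian noise is added per observation.
#'
#' @param n_genes Number of genes.
#' @param time_points Ordered numeric time labels (days); at least 3.
#' @param n_replicates Replicate hybridizations per time point.
#' @param frac_up,frac_down Fractions of genes with planted rising / falling
#'   trajectories; must sum to at most 1.
#' @param max_change Planted total log2 change from baseline to the final
#'   time point.
#' @param noise_sd Per-observation Gaussian noise sd (log2 units).
#' @param seed Integer seed.
#'
#' @return A list with components
#'   \describe{
#'     \item{expr}{tibble, first column `gene_id`, then one column per
#'       (time point, replicate) named `d<day>_r<rep>`.}
#'     \item{time}{numeric vector mapping each value column to its day.}
#'     \item{truth}{tibble with `gene_id`, `is_deg`, `direction`, `effect`.}
#'   }
#' @examples
#' sim <- simulate_timeseries(n_genes = 50, seed = 3)
#' sim$time
#' @export
simulate_timeseries <- function(n_genes = 500,
                                time_points = seq(4, 24, by = 4),
                                n_replicates = 1,
                                frac_up = 0.1,
                                frac_down = 0.1,
                                max_change = 3,
                                noise_sd = 0.2,
                                seed = 1) {
  check_fraction(frac_up, "frac_up")
  check_fraction(frac_down, "frac_down")
  if (frac_up + frac_down > 1) abort("`frac_up` + `frac_down` must be <= 1.")
  if (length(time_points) < 3L) abort("need at least 3 time points.")
  if (is.unsorted(time_points, strictly = TRUE)) {
    abort("`time_points` must be strictly increasing.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (n_replicates < 1L) abort("`n_replicates` must be at least 1.")

  nt <- length(time_points)
  withr::with_seed(seed, {
    gene_id <- sprintf("g%05d", seq_len(n_genes))
    n_up <- round(frac_up * n_genes)
    n_down <- round(frac_down * n_genes)
    direction <- integer(n_genes)
    pick <- sample.int(n_genes, n_up + n_down)
    direction[pick[seq_len(n_up)]] <- 1L
    if (n_down > 0) direction[pick[n_up + seq_len(n_down)]] <- -1L
    effect <- direction * max_change

    baseline <- rnorm(n_genes, 0, 0.3)
    ramp <- (seq_len(nt) - 1) / (nt - 1)          # 0 at baseline, 1 at end
    mu <- outer(baseline, rep(1, nt)) + outer(effect, ramp)

    cols <- as.vector(t(outer(time_points, seq_len(n_replicates),
                              function(d, r) sprintf("d%d_r%d", d, r))))
    time <- rep(time_points, each = n_replicates)
    x <- mu[, rep(seq_len(nt), each = n_replicates), drop = FALSE] +
      matrix(rnorm(n_genes * nt * n_replicates, 0, noise_sd),
             n_genes, nt * n_replicates)
    dimnames(x) <- list(gene_id, cols)

    list(
      expr = matrix_to_tibble(x, id_col = "gene_id"),
      time = time,
      truth = tibble(gene_id = gene_id,
                     is_deg = direction != 0L,
                     direction = direction,
                     effect = effect)
    )
  })
}

#' Split samples into physical-ability groups by maximum velocity
#'
#' Labels an animal `"low"` physical ability when its maximum velocity (MV,
#' peak locomotion speed in a 30-second recording) is strictly below the
#' threshold, and `"high"` otherwise. The default threshold of 0.22 mm/sec is
#' the minimum MV observed at day 1 of adulthood; the comparison is a strict
#' "less than", so an MV of exactly 0.22 is classed `"high"`.
#'
#' @param mv Numeric vector of maximum velocities in mm/sec; must be
#'   non-negative.
#' @param threshold Velocity threshold in mm/sec.
#' @return Character vector of `"low"`/`"high"` labels, same length as `mv`.
#' @examples
#' classify_by_mv(c(0.10, 0.21, 0.22, 0.35))
#' @export
classify_by_mv <- function(mv, threshold = 0.22) {
  if (length(mv) == 0L) return(character(0))
  if (!is.numeric(mv) || any(is.na(mv))) abort("`mv` must be numeric without NA.")
  if (any(mv < 0)) abort("maximum velocity cannot be negative.")
  check_positive(threshold, "threshold")
  ifelse(mv < threshold, "low", "high")
}
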