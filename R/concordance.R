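#' Cross-tabulate two directional gene sets
#'
#' Counts the concordant (up-up, down-down) and discordant (up-down, down-up)
#' intersections of two directional DEG sets -- e.g. genes up- or
#' down-regulated in low physical-ability worms versus in chronologically
#' aged worms -- and reports the percentage of set A's DEGs that change
#' concordantly in set B.
#'
#' @param set_a,set_b Data frames with columns `gene` and `direction`
#'   (`"up"`/`"down"`); within one set a gene may not appear with both
#'   directions.
#' @param denominator Denominator of `percent_overlap`: set A's DEG total
#'   (default), set B's, or the union of both sets.
#' @return A one-row tibble with the four intersection counts `n_up_up`,
#'   `n_down_down`, `n_up_down`, `n_down_up`, the set sizes, the universe
#'   size (distinct genes across both sets) and `percent_overlap`.
#' @examples
#' a <- tibble::tibble(gene = c("g1", "g2", "g3", "g4"),
#'                     direction = c("up", "up", "up", "down"))
#' b <- tibble::tibble(gene = c("g2", "g3", "g5", "g4", "g6"),
#'                     direction = c("up", "up", "up", "down", "down"))
#' overlap_table(a, b)
#' @export
overlap_table <- function(set_a, set_b,
                          denominator = c("a", "b", "union")) {
  denominator <- match.arg(denominator)
  dir_sets <- function(s, name) {
    if (!all(c("gene", "direction") %in% names(s))) {
      abort(sprintf("set %s needs columns `gene` and `direction`.", name))
    }
    if (!all(s$direction %in% c("up", "down"))) {
      abort(sprintf("set %s has directions other than up/down.", name))
    }
    up <- unique(s$gene[s$direction == "up"])
    down <- unique(s$gene[s$direction == "down"])
    if (length(intersect(up, down)) > 0L) {
      abort(sprintf("set %s lists genes as both up and down.", name))
    }
    list(up = up, down = down)
  }
  a <- dir_sets(set_a, "A")
  b <- dir_sets(set_b, "B")

  n_up_up <- length(intersect(a$up, b$up))
  n_down_down <- length(intersect(a$down, b$down))
  n_up_down <- length(intersect(a$up, b$down))
  n_down_up <- length(intersect(a$down, b$up))

  n_a <- length(a$up) + length(a$down)
  n_b <- length(b$up) + length(b$down)
  n_union <- length(unique(c(a$up, a$down, b$up, b$down)))
  denom <- switch(denominator, a = n_a, b = n_b, union = n_union)
  percent_overlap <- if (denom == 0) NA_real_ else {
    100 * (n_up_up + n_down_down) / denom
  }

  tibble(
    n_up_up = n_up_up, n_down_down = n_down_down,
    n_up_down = n_up_down, n_down_up = n_down_up,
    n_a = n_a, n_b = n_b, n_universe = n_union,
    percent_overlap = percent_overlap,
    denominator = denominator
  )
}

#' Percentage of genes called differentially expressed
#'
#' The DEG fraction of a platform: `100 * (n_up + n_down) / n_total`,
#' reported to one decimal place. With the published counts of 1075
#' up-regulated and 1091 down-regulated genes on a 20,115-gene chip this is
#' 10.8.
#'
#' @param n_up,n_down Numbers of up- and down-regulated genes.
#' @param n_total Total genes assayed; must be positive and at least
#'   `n_up + n_down`.
#' @return Percentage rounded to one decimal.
#' @examples
#' deg_fraction(1075, 1091, 20115)
#' @export
deg_fraction <- function(n_up, n_down, n_total) {
  if (any(n_total <= 0)) abort("`n_total` must be positive.")
  if (any(n_up < 0) || any(n_down < 0)) abort("counts must be non-negative.")
  if (any(n_up + n_down > n_total)) {
    abort("`n_up + n_down` cannot exceed `n_total`.")
  }
  round(100 * (n_up + n_down) / n_total, 1)
}
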