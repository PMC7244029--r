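# Internal helpers shared across the pipeline stages.

# Coerce a probes-x-samples table to a numeric matrix with probe ids as
# rownames. Accepts a data frame whose first column is the id column, or a
# numeric matrix that already has rownames.
as_expr_matrix <- function(data, what = "expression matrix") {
  if (is.matrix(data)) {
    if (!is.numeric(data)) abort(sprintf("%s must be numeric.", what))
    if (is.null(rownames(data))) {
      rownames(data) <- sprintf("row_%d", seq_len(nrow(data)))
    }
    if (is.null(colnames(data))) {
      colnames(data) <- sprintf("s%d", seq_len(ncol(data)))
    }
    return(data)
  }
  if (!is.data.frame(data)) {
    abort(sprintf("%s must be a data frame or a numeric matrix.", what))
  }
  if (ncol(data) < 2L) abort(sprintf("%s needs an id column plus values.", what))
  ids <- as.character(data[[1L]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("duplicate ids in %s: %s", what,
                  paste(head(dup, 5L), collapse = ", ")))
  }
  m <- as.matrix(data[, -1L, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("%s has non-numeric value columns.", what))
  rownames(m) <- ids
  m
}

# Rebuild the tibble form (id column first) from a matrix.
matrix_to_tibble <- function(m, id_col = "probe_id") {
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(!!id_col := rownames(m)), out)
  out
}

check_finite <- function(m, what = "expression matrix") {
  if (!all(is.finite(m))) {
    abort(sprintf("%s contains non-finite values.", what))
  }
  invisible(m)
}

# Row-wise medians of a numeric matrix without per-row apply() overhead:
# a single order() groups each row's values in ascending order.
row_medians <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  if (n == 0L) return(numeric(0))
  if (k == 1L) return(as.vector(x))
  o <- order(row(x), x)
  s <- matrix(x[o], nrow = n, ncol = k, byrow = TRUE)
  if (k %% 2L == 1L) {
    s[, (k + 1L) %/% 2L]
  } else {
    (s[, k %/% 2L] + s[, k %/% 2L + 1L]) / 2
  }
}

# Row-wise pooled-variance Student t for two column blocks of one matrix.
# Zero pooled variance: equal means give t = 0, unequal means a signed Inf.
row_t_pooled <- function(a, b) {
  na <- ncol(a)
  nb <- ncol(b)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  ssa <- rowSums((a - ma)^2)
  ssb <- rowSums((b - mb)^2)
  sp2 <- (ssa + ssb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  t[se == 0 & (ma - mb) == 0] <- 0
  t
}

# Independently permute the values within every row of a matrix.
shuffle_within_rows <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  ord <- t(apply(matrix(runif(n * m), n, m), 1L, order))
  matrix(x[cbind(rep(seq_len(n), times = m), c(ord))], n, m,
         dimnames = dimnames(x))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1].", name))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive value.", name))
  }
  invisible(x)
}
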