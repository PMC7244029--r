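#' Read and write tab-delimited expression matrices
#'
#' The on-disk dialect is plain TSV (UTF-8, `.` decimal): a header row of
#' sample ids, first column the probe/gene id, every other cell a finite
#' decimal. `read_expression_tsv()` rejects duplicate ids, non-numeric cells
#' and ragged rows with an informative error.
#'
#' @param path File path.
#' @return `read_expression_tsv()`: a tibble with the id column first;
#'   `write_expression_tsv()`: `path`, invisibly.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- suppressWarnings(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
  prob <- readr::problems(out)
  if (nrow(prob) > 0L) {
    abort(sprintf("parse error in %s at line %d: expected %s, got %s",
                  path, prob$row[1] + 1L, prob$expected[1], prob$actual[1]))
  }
  if (ncol(out) < 2L) abort(sprintf("%s has no value columns.", path))
  ids <- out[[1L]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("duplicate ids in %s: %s", path,
                  paste(head(dup, 5L), collapse = ", ")))
  }
  vals <- out[, -1L, drop = FALSE]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad) > 0L) {
    abort(sprintf("non-numeric value column(s) in %s: %s", path,
                  paste(bad, collapse = ", ")))
  }
  if (!all(vapply(vals, function(v) all(is.finite(v)), logical(1)))) {
    abort(sprintf("%s contains missing or non-finite values.", path))
  }
  out
}

#' @rdname read_expression_tsv
#' @param data Data frame to write (id column first).
#' @export
write_expression_tsv <- function(data, path) {
  readr::write_tsv(data, path, progress = FALSE)
  invisible(path)
}

#' Read a GEO series-matrix file
#'
#' Parses the plain-text series-matrix format distributed by the Gene
#' Expression Omnibus: `!`-prefixed metadata lines followed by a value table
#' between `!series_matrix_table_begin` and `!series_matrix_table_end`,
#' tab-separated with quoted sample ids. Quotes are stripped; metadata lines
#' are returned alongside the matrix.
#'
#' @param path Path to an uncompressed series-matrix text file.
#' @return A list with `expr` (tibble, `probe_id` first) and `metadata`
#'   (tibble of the `!Sample_*` / `!Series_*` header lines, columns `key` and
#'   `value`).
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    abort(sprintf("%s: missing or malformed series_matrix_table delimiters.",
                  path))
  }
  table_lines <- gsub('"', "", lines[(begin + 1L):(end - 1L)], fixed = TRUE)
  expr <- readr::read_tsv(I(table_lines), show_col_types = FALSE,
                          progress = FALSE)
  names(expr)[1] <- "probe_id"

  meta_lines <- grep("^!", lines[seq_len(begin - 1L)], value = TRUE)
  meta <- purrr::map_dfr(meta_lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    tibble(key = sub("^!", "", parts[1]),
           value = paste(gsub('"', "", parts[-1], fixed = TRUE),
                         collapse = "\t"))
  })
  list(expr = expr, metadata = meta)
}

#' Run the whole integrative aging-DEG analysis on synthetic data
#'
#' Convenience driver wiring every stage together: simulate a two-group
#' physical-ability experiment and an aging time course (sharing a gene-id
#' universe when the sizes match), run the two-group pipeline
#' ([deg_two_group()]) and the time-series pipeline ([deg_timeseries()]),
#' cross-tabulate the two directional DEG sets ([overlap_table()]), and
#' return a self-describing report of all counts, thresholds and seeds.
#'
#' @param config Named list of overrides, merged over the defaults; see
#'   `full_config()` for the fields (`two_group`, `timeseries`, `deg`, `ts`,
#'   `seed`).
#' @param out Optional path; when given the report is also written as JSON.
#' @return The report as a named list (invisibly when `out` is given).
#' @examples
#' rep <- run_full(list(two_group = list(n_probes = 200),
#'                      timeseries = list(n_genes = 200),
#'                      deg = list(B = 50)))
#' rep$two_group$percent_deg
#' @export
run_full <- function(config = list(), out = NULL) {
  cfg <- full_config(config)
  if (cfg$deg$alpha <= 0 || cfg$deg$alpha >= 1) {
    abort("`alpha` must be in (0, 1).")
  }

  sim2 <- do.call(simulate_two_group, cfg$two_group)
  fit2 <- deg_two_group(sim2$expr, sim2$metadata,
                        B = cfg$deg$B, alpha = cfg$deg$alpha,
                        fc_cut = cfg$deg$fc_cut, seed = cfg$deg$seed)
  g2 <- glance(fit2)

  simt <- do.call(simulate_timeseries, cfg$timeseries)
  fitt <- deg_timeseries(simt$expr, simt$time,
                         fc_cutoff = cfg$ts$fc_cutoff, k = cfg$ts$k,
                         seed = cfg$ts$seed)
  gt <- glance(fitt)

  tab2 <- tidy(fit2)
  set_a <- tibble(gene = tab2$probe_id[tab2$call != "none"],
                  direction = as.character(tab2$call[tab2$call != "none"]))
  tabt <- tidy(fitt)
  keep <- !is.na(tabt$class) & tabt$class %in% c("up", "down")
  set_b <- tibble(gene = tabt$gene_id[keep],
                  direction = as.character(tabt$class[keep]))
  conc <- overlap_table(set_a, set_b)

  report <- list(
    thresholds = list(alpha = cfg$deg$alpha, fc_cut = cfg$deg$fc_cut,
                      ts_fc_cutoff = cfg$ts$fc_cutoff,
                      mv_threshold = 0.22),
    seeds = list(two_group = cfg$two_group$seed,
                 timeseries = cfg$timeseries$seed,
                 deg = cfg$deg$seed, ts = cfg$ts$seed),
    B = cfg$deg$B,
    k = cfg$ts$k,
    two_group = as.list(g2[c("n_probes", "n_present", "n_up", "n_down",
                             "percent_deg")]),
    timeseries = as.list(gt[c("n_genes", "n_deg", "n_up", "n_down",
                              "n_others")]),
    concordance = as.list(conc[c("n_up_up", "n_down_down", "n_up_down",
                                 "n_down_up", "percent_overlap")])
  )
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}

# Default full-pipeline configuration, with user overrides merged shallowly
# per stage.
full_config <- function(overrides = list()) {
  defaults <- list(
    two_group = list(n_probes = 2000, n_per_group = 5, frac_absent = 0.3,
                     frac_deg = 0.1, effect_size = 2, noise_sd = 0.3,
                     seed = 1),
    timeseries = list(n_genes = 2000, frac_up = 0.1, frac_down = 0.1,
                      max_change = 3, noise_sd = 0.2, seed = 1),
    deg = list(B = 200, alpha = 0.05, fc_cut = 0.58, seed = 1),
    ts = list(fc_cutoff = 2.5, k = 40, seed = 1)
  )
  for (stage in names(overrides)) {
    if (!stage %in% names(defaults)) {
      abort(sprintf("unknown config stage '%s'.", stage))
    }
    for (field in names(overrides[[stage]])) {
      defaults[[stage]][[field]] <- overrides[[stage]][[field]]
    }
  }
  defaults
}
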