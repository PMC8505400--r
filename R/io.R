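#' Read a wide sample table from CSV
#'
#' One row per site x phase; columns `site_id`, `phase`, then one column
#' per parameter code. Empty cells become declared-absent (`NA`) values.
#' Unknown parameter columns raise a warning, not an error; duplicate
#' (site, phase) pairs and unparseable numbers are format errors.
#'
#' @param path CSV file path.
#' @param standards A `wq_standards` object to resolve parameter columns
#'   against (default registry if omitted).
#' @return Wide tibble of validated samples.
#' @export
read_samples <- function(path, standards = default_standards()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("site_id", "phase") %in% names(df)))
    stop("format error: sample table needs site_id and phase columns")
  param_cols <- setdiff(names(df), c("site_id", "phase", "collected"))
  unknown <- setdiff(param_cols, standards$parameters$code)
  if (length(unknown))
    warning("unknown parameter column(s) ignored by the registry: ",
            paste(unknown, collapse = ", "))
  for (col in param_cols) {
    if (!is.numeric(df[[col]])) {
      bad <- which(!is.na(df[[col]]) &
                     is.na(suppressWarnings(as.numeric(df[[col]]))))
      if (length(bad))
        stop("format error: unparseable number in column '", col,
             "', row(s) ", paste(bad, collapse = ", "))
      df[[col]] <- as.numeric(df[[col]])
    }
  }
  key <- paste(df$site_id, df$phase)
  if (anyDuplicated(key))
    stop("format error: duplicated (site_id, phase) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  for (i in seq_len(nrow(df)))
    validate_sample(unlist(df[i, intersect(param_cols,
                                           standards$parameters$code)]),
                    standards)
  tibble::as_tibble(df)
}

#' Write a wide sample table to CSV
#'
#' Inverse of [read_samples()]: UTF-8, comma-separated, "." decimal point.
#'
#' @param samples Wide sample tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  readr::write_csv(samples, path, progress = FALSE)
  invisible(path)
}

#' Percentage of samples in each class, per index and phase
#'
#' The share (in percent, two decimals at presentation) of samples falling
#' in each qualitative class, per index and phase -- the campaign-style
#' class-distribution table.
#'
#' @param index_results Tidy index tibble from [compute_indices()].
#' @return Tibble with columns `index`, `phase`, `class_label`, `n`, `pct`;
#'   `pct` sums to 100 within each index x phase.
#' @export
class_percentage_table <- function(index_results) {
  d <- index_results[!is.na(index_results$value), ]
  agg <- stats::aggregate(list(n = d$value),
                          by = list(index = d$index, phase = d$phase,
                                    class_label = d$class_label),
                          FUN = length)
  tot <- stats::aggregate(list(total = d$value),
                          by = list(index = d$index, phase = d$phase),
                          FUN = length)
  m <- merge(agg, tot, by = c("index", "phase"))
  m$pct <- m$n / m$total * 100
  m <- m[order(m$index, m$phase, -m$n), ]
  tibble::as_tibble(m[, c("index", "phase", "class_label", "n", "pct")])
}

#' Run the full assessment pipeline
#'
#' Orchestrates the whole analysis on a validated sample table: per-sample
#' index values and classes for all four indices, the per-phase class
#' percentage table, parameter-wise comparisons of each non-baseline phase
#' against the baseline, per-phase Pearson correlation matrices, and the
#' across-phase ANOVA table. Optionally writes every table as CSV.
#'
#' @param samples Wide sample tibble.
#' @param standards A `wq_standards` object.
#' @param baseline Baseline phase for comparisons (default
#'   `"pre_lockdown"`).
#' @param out_dir Optional directory; when given, each result table is
#'   written there as CSV (`indices.csv`, `class_table.csv`,
#'   `comparison_<phase>.csv`, `correlations_<phase>.csv`, `anova.csv`).
#' @return List of class `wq_results`: `indices`, `class_table`,
#'   `comparisons` (named list of tibbles), `correlations` (named list),
#'   `anova`, `log` (character vector of per-sample decisions).
#' @export
run_pipeline <- function(samples, standards = default_standards(),
                         baseline = "pre_lockdown", out_dir = NULL) {
  idx <- compute_indices(samples, standards)
  log <- attr(idx, "log")
  class_table <- class_percentage_table(idx)
  phases <- unique(samples$phase)
  others <- setdiff(phases, baseline)
  comparisons <- list()
  if (baseline %in% phases) {
    for (ph in others)
      comparisons[[ph]] <- compare_phases(samples, baseline, ph)
  } else {
    log <- c(log, paste0("baseline phase '", baseline,
                         "' absent; comparisons skipped"))
  }
  correlations <- list()
  for (ph in phases) {
    correlations[[ph]] <- tryCatch(
      correlation_matrix(samples, ph),
      error = function(e) {
        log <<- c(log, paste0("correlations skipped for ", ph, ": ",
                              conditionMessage(e)))
        NULL
      })
  }
  anova <- if (length(phases) >= 2) anova_table(samples) else NULL
  res <- structure(list(indices = idx, class_table = class_table,
                        comparisons = comparisons,
                        correlations = correlations,
                        anova = anova, log = log),
                   class = "wq_results")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(idx, file.path(out_dir, "indices.csv"))
    readr::write_csv(class_table, file.path(out_dir, "class_table.csv"))
    for (ph in names(comparisons))
      readr::write_csv(comparisons[[ph]],
                       file.path(out_dir, paste0("comparison_", ph, ".csv")))
    for (ph in names(correlations))
      if (!is.null(correlations[[ph]]))
        readr::write_csv(correlations[[ph]],
                         file.path(out_dir,
                                   paste0("correlations_", ph, ".csv")))
    if (!is.null(anova))
      readr::write_csv(anova, file.path(out_dir, "anova.csv"))
    if (length(log))
      writeLines(log, file.path(out_dir, "pipeline.log"))
  }
  res
}

#' @export
print.wq_results <- function(x, ...) {
  cat("Water quality assessment results\n")
  cat("  samples:", nrow(x$indices) / 4, " index rows:", nrow(x$indices), "\n")
  cat("  phases:", paste(unique(x$indices$phase), collapse = ", "), "\n")
  if (length(x$log)) cat("  log entries:", length(x$log), "\n")
  invisible(x)
}
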