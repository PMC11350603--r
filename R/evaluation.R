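# Counting metrics (MAE / RMSE), count extraction from density maps, and
# the benchmark-table comparison arithmetic (percent reductions and
# absolute differences between models).

#' Count from a density map
#'
#' The estimated object count of a density map is its integral, i.e. the
#' grid sum; it is invariant under sum-preserving downsampling.
#'
#' @param density density map (matrix).
#' @return scalar count (real-valued; not rounded).
#' @export
count_from_density <- function(density) {
  sum(density_values(as.matrix(density)))
}

#' Counting error metrics
#'
#' `MAE = mean |P_i - G_i|` and `RMSE = sqrt(mean (P_i - G_i)^2)` over
#' per-image (predicted, actual) count pairs. Predicted counts enter as
#' real values; no rounding is applied.
#'
#' @param pairs two-column matrix or data.frame: predicted, actual.
#' @return an `eval_result` list with `mae`, `rmse` and `n`.
#' @export
compute_metrics <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) stop_cfg("no (predicted, actual) pairs supplied")
  if (ncol(pairs) != 2) stop_cfg("pairs must have two columns")
  err <- pairs[, 1] - pairs[, 2]
  structure(list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
                 n = nrow(pairs)), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("MAE %.4f  RMSE %.4f  (n = %d)\n", x$mae, x$rmse, x$n))
  invisible(x)
}

#' Percent reduction of an error metric
#'
#' `100 * (baseline - improved) / baseline`, rounded half-up to two
#' decimals to match conventional benchmark reporting.
#'
#' @param baseline reference value (> 0).
#' @param improved new value.
#' @return percentage, two decimals.
#' @export
percent_reduction <- function(baseline, improved) {
  if (!is.finite(baseline) || baseline <= 0)
    stop_cfg("baseline must be a positive number")
  round_half_up(100 * (baseline - improved) / baseline, 2)
}

#' Read a benchmark comparison table
#'
#' Plain CSV with columns `model`, `setting` (a labeled percentage such
#' as `"5%"`, or `"full"` for fully supervised rows), `mae`, `rmse`.
#' Copies of published new-shoot counting benchmarks ship with the
#' package; see `system.file("extdata", package = "shootcount")`.
#'
#' @param path CSV file.
#' @return a `data.frame`.
#' @export
read_comparison_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("model", "setting", "mae", "rmse")
  if (!all(need %in% names(tab)))
    stop_cfg("comparison table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(tab$mae)) || any(tab$mae <= 0) || any(tab$rmse <= 0))
    stop_cfg("mae and rmse must be positive")
  tab
}

table_row <- function(tab, model, setting) {
  i <- which(tab$model == model & tab$setting == setting)
  if (length(i) != 1)
    stop_cfg("row not found (or ambiguous) in comparison table: model='",
             model, "', setting='", setting, "'")
  tab[i, ]
}

#' Comparison report between benchmark rows
#'
#' For each requested pair of rows, reports the percent reduction and
#' absolute difference of the chosen metric from the baseline row to the
#' improved row.
#'
#' @param table data.frame from [read_comparison_table()].
#' @param pairs data.frame with columns `baseline_model`,
#'   `baseline_setting`, `improved_model`, `improved_setting`, `metric`
#'   (`"mae"` or `"rmse"`).
#' @return data.frame with the inputs plus `baseline`, `improved`,
#'   `reduction_pct` and `difference` columns; printing gives a
#'   human-readable report.
#' @export
comparison_report <- function(table, pairs) {
  need <- c("baseline_model", "baseline_setting", "improved_model",
            "improved_setting", "metric")
  if (!all(need %in% names(pairs)))
    stop_cfg("pairs needs columns: ", paste(need, collapse = ", "))
  out <- pairs
  out$baseline <- NA_real_; out$improved <- NA_real_
  out$reduction_pct <- NA_real_; out$difference <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    m <- match.arg(pairs$metric[i], c("mae", "rmse"))
    b <- table_row(table, pairs$baseline_model[i], pairs$baseline_setting[i])
    a <- table_row(table, pairs$improved_model[i], pairs$improved_setting[i])
    out$baseline[i] <- b[[m]]
    out$improved[i] <- a[[m]]
    out$reduction_pct[i] <- percent_reduction(b[[m]], a[[m]])
    out$difference[i] <- round_half_up(a[[m]] - b[[m]], 2)
  }
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "%s %s (%s %.2f) vs %s %s (%.2f): reduction %.2f%%, difference %.2f\n",
      x$improved_model[i], x$improved_setting[i], toupper(x$metric[i]),
      x$improved[i], x$baseline_model[i], x$baseline_setting[i],
      x$baseline[i], x$reduction_pct[i], x$difference[i]))
  }
  invisible(x)
}

#' Write a comparison report as CSV
#'
#' @param report a `comparison_report`.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
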