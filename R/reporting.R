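#' Group summaries of morphometric and density-distribution results
#'
#' Aggregates per-sample results into per-group descriptive statistics:
#' mean, sample standard deviation and quartiles (min, Q1, median, Q3, max;
#' linear-interpolation quantile convention, `type = 7`) for each of the
#' seven morphometric indices and the five MDDr parameters. No hypothesis
#' tests are computed - the report is descriptive, mirroring mean +/- SD
#' tables and box plots.
#'
#' @param samples a data.frame with one row per sample: a `group` column
#'   plus any of the index columns (`coll_s_over_coll_v`, `coll_v_over_tv`,
#'   `th_um`, `nr_per_mm`, `sp_um`, `da`, `conn_d`, `mdd_peak`, `mdd_mean`,
#'   `mdd_fwhm`, `mdd_low`, `mdd_high`). See [sample_row()] for building
#'   rows from result objects.
#' @param csv optional path; when given, the summary is also written as CSV.
#' @return An object of class `group_summary`: a data.frame with columns
#'   `group`, `index`, `n`, `mean`, `sd`, `min`, `q1`, `median`, `q3`,
#'   `max`, `sd_defined`. Groups with a single sample report `sd = 0` with
#'   `sd_defined = FALSE`.
#' @export
summarize_groups <- function(samples, csv = NULL) {
  if (!is.data.frame(samples) || !"group" %in% names(samples))
    stop("`samples` must be a data.frame with a `group` column")
  idx_cols <- intersect(c(morpho_index_names, mdd_param_names),
                        names(samples))
  if (length(idx_cols) == 0L) stop("no index columns found")
  groups <- unique(samples$group)
  out <- list()
  for (g in groups) {
    sub <- samples[samples$group == g, , drop = FALSE]
    for (ix in idx_cols) {
      v <- sub[[ix]]
      v <- v[!is.na(v)]
      if (length(v) == 0L) next
      qs <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
      out[[length(out) + 1L]] <- data.frame(
        group = g, index = ix, n = length(v), mean = mean(v),
        sd = if (length(v) > 1) sd(v) else 0,
        min = qs[1], q1 = qs[2], median = qs[3], q3 = qs[4], max = qs[5],
        sd_defined = length(v) > 1)
    }
  }
  res <- do.call(rbind, out)
  # deterministic row order: morphometry indices first, then MDD parameters
  res$index <- factor(res$index,
                      levels = c(morpho_index_names, mdd_param_names))
  res <- res[order(res$group, res$index), , drop = FALSE]
  res$index <- as.character(res$index)
  rownames(res) <- NULL
  class(res) <- c("group_summary", "data.frame")
  if (!is.null(csv)) write.csv(res, csv, row.names = FALSE)
  res
}

#' Build one sample row for [summarize_groups()]
#'
#' @param group group label (e.g. `"Ctr"` or `"L"`).
#' @param morpho a `morphometry_result` or `subvolume_report` (aggregated
#'   means are used), or `NULL`.
#' @param mdd an `mdd_parameters` object, or `NULL`.
#' @return A one-row data.frame.
#' @export
sample_row <- function(group, morpho = NULL, mdd = NULL) {
  row <- data.frame(group = group)
  if (inherits(morpho, "subvolume_report")) {
    for (ix in morpho_index_names)
      row[[ix]] <- morpho$aggregate$mean[morpho$aggregate$index == ix]
  } else if (inherits(morpho, "morphometry_result")) {
    for (ix in morpho_index_names) row[[ix]] <- morpho[[ix]]
  }
  if (inherits(mdd, "mdd_parameters")) {
    row$mdd_peak <- mdd$peak
    row$mdd_mean <- mdd$mean
    row$mdd_fwhm <- mdd$fwhm
    row$mdd_low <- mdd$low
    row$mdd_high <- mdd$high
  }
  row
}

#' @export
print.group_summary <- function(x, ...) {
  cat("<group_summary>\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
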