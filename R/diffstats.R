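#' Volcano statistics for a two-group comparison
#'
#' Per feature: the ratio of group means (case over control) and a
#' two-sample t-test p-value (Welch by default; `var_equal = TRUE` gives
#' the pooled Student test). A feature is called significant when
#' `p < 0.05` and its mean fold change lies outside (0.7, 1.5) -- the
#' usual volcano gate on raw p-values; a Benjamini-Hochberg FDR column is
#' emitted for information but does not gate the call. Signed
#' `log2(fold)` and `-log10(p)` columns are included for plotting.
#'
#' @param table a [feature_table] or a features-by-samples matrix.
#' @param groups named character vector `sample_id -> group label` (only
#'   samples named here enter the test).
#' @param case,control the two group labels to compare.
#' @param p_cut,fold_lo,fold_hi significance gate parameters.
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @return data frame with one row per feature: `feature_id`,
#'   `mean_case`, `mean_control`, `mean_fold`, `log2fc`, `p_value`,
#'   `minus_log10_p`, `bh_fdr`, `significant`, `flagged` (fold undefined,
#'   e.g. zero control mean).
#' @export
volcano_stats <- function(table, groups, case, control,
                          p_cut = 0.05, fold_lo = 0.7, fold_hi = 1.5,
                          var_equal = FALSE) {
  v <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  ids <- rownames(v) %||% sprintf("F%05d", seq_len(nrow(v)))
  case_cols <- names(groups)[groups == case]
  ctrl_cols <- names(groups)[groups == control]
  stop_if(length(case_cols) < 2 || length(ctrl_cols) < 2,
          "need at least 2 samples per group")
  xa <- v[, case_cols, drop = FALSE]
  xb <- v[, ctrl_cols, drop = FALSE]
  n <- nrow(v)
  p <- mean_a <- mean_b <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- xa[i, ][!is.na(xa[i, ])]
    b <- xb[i, ][!is.na(xb[i, ])]
    mean_a[i] <- mean(a); mean_b[i] <- mean(b)
    p[i] <- tryCatch(
      stats::t.test(a, b, var.equal = var_equal)$p.value,
      error = function(e) NA_real_)
  }
  fold <- ifelse(is.finite(mean_b) & mean_b > 0, mean_a / mean_b, NA_real_)
  flagged <- !is.finite(fold)
  sig <- !flagged & !is.na(p) & p < p_cut &
    (fold < fold_lo | fold > fold_hi)
  data.frame(feature_id = ids,
             mean_case = mean_a, mean_control = mean_b,
             mean_fold = fold, log2fc = log2(fold),
             p_value = p, minus_log10_p = -log10(p),
             bh_fdr = stats::p.adjust(p, "BH"),
             significant = sig, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Select the top differential features by p-value
#'
#' The `n` smallest p-values; ties are broken by larger absolute log2
#' fold change, then by feature id.
#'
#' @param volcano_rows output of [volcano_stats()].
#' @param n number of features to keep.
#' @return character vector of `n` feature ids, in selection order.
#' @export
select_top_features <- function(volcano_rows, n = 300L) {
  stop_if(!is_count(n) || n <= 0, "n must be a positive count")
  stop_if(n > nrow(volcano_rows),
          "n exceeds the number of features (", nrow(volcano_rows), ")")
  ord <- order(volcano_rows$p_value, -abs(volcano_rows$log2fc),
               volcano_rows$feature_id, na.last = TRUE)
  volcano_rows$feature_id[ord][seq_len(n)]
}

#' Heat-map ratio matrix relative to the control-group average
#'
#' For each selected feature, every individual's value is divided by the
#' feature's control-group mean, so control rows average to 1 by
#' construction. Each cell is also binned on a fixed log10-uniform color
#' scale: 9 bins spanning ratios 0.1 to 10 plus the two overflow bins
#' (`< 0.1`, brightest green, and `> 10`, brightest red). Features whose
#' control mean is zero or undefined are dropped with a message.
#'
#' @param table a [feature_table] or matrix.
#' @param feature_ids features to include, in display (row) order --
#'   typically from [select_top_features()], i.e. ascending p-value.
#' @param control_ids sample ids forming the control group.
#' @param sample_ids columns to include, in display order; defaults to
#'   all columns.
#' @return a `heatmap_matrix`: list with `ratio` and `bin` matrices
#'   (bins indexed 0..10, 5 = ratio 1), `bin_labels`, `dropped`.
#' @export
heatmap_ratio_matrix <- function(table, feature_ids, control_ids,
                                 sample_ids = NULL) {
  v <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  stop_if(length(control_ids) == 0, "control group must be non-empty")
  missing <- setdiff(feature_ids, rownames(v))
  stop_if(length(missing) > 0, "features not in table: ",
          paste(utils::head(missing, 5), collapse = ", "))
  sample_ids <- sample_ids %||% colnames(v)
  v <- v[feature_ids, , drop = FALSE]
  ctrl_mean <- rowMeans(v[, control_ids, drop = FALSE], na.rm = TRUE)
  bad <- !is.finite(ctrl_mean) | ctrl_mean <= 0
  if (any(bad))
    message(sum(bad), " feature(s) dropped: undefined control mean")
  v <- v[!bad, sample_ids, drop = FALSE]
  ratio <- v / ctrl_mean[!bad]
  edges <- 10 ^ seq(-1, 1, length.out = 10)
  bin <- matrix(findInterval(ratio, edges), nrow(ratio),
                dimnames = dimnames(ratio))
  labels <- c("<0.1",
              sprintf("%.2f-%.2f", edges[-10], edges[-1]),
              ">10")
  structure(list(ratio = ratio, bin = bin, bin_labels = labels,
                 control_ids = control_ids,
                 dropped = feature_ids[bad]),
            class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat(sprintf("Heat-map ratio matrix: %d features x %d samples\n",
              nrow(x$ratio), ncol(x$ratio)))
  cat(sprintf("  ratio range %.3g .. %.3g; %d bins (<0.1 .. >10)\n",
              min(x$ratio, na.rm = TRUE), max(x$ratio, na.rm = TRUE),
              length(x$bin_labels)))
  invisible(x)
}
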