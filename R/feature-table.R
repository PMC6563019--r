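#' Aligned feature table
#'
#' Container for an aligned features-by-samples matrix of (possibly
#' normalized) peak areas together with per-feature consensus coordinates.
#'
#' @param values numeric matrix, features in rows, samples in columns;
#'   `NA` marks a sample that contributed no peak to the feature.
#' @param features data frame with at least `feature_id`, `rt` (minutes),
#'   `mz` (Da); typically also `sn` (representative signal-to-noise) and
#'   `n_detected`.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(values, features) {
  stopifnot(is.matrix(values), is.data.frame(features),
            nrow(values) == nrow(features),
            all(c("feature_id", "rt", "mz") %in% names(features)))
  stop_if(anyDuplicated(features$feature_id) > 0,
          "duplicate feature ids in feature table")
  rownames(values) <- features$feature_id
  rownames(features) <- features$feature_id
  structure(list(values = values, features = features),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d features x %d samples (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  cat(sprintf("  rt %.2f-%.2f min, m/z %.2f-%.2f Da\n",
              min(x$features$rt), max(x$features$rt),
              min(x$features$mz), max(x$features$mz)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

# keep (or drop) features by id; preserves order of the table
ft_subset <- function(table, ids, drop = FALSE) {
  keep <- if (drop) setdiff(table$features$feature_id, ids)
  else intersect(table$features$feature_id, ids)
  feature_table(table$values[keep, , drop = FALSE],
                table$features[keep, , drop = FALSE])
}

#' Impute missing feature areas as half the feature minimum
#'
#' Missing cells (runs contributing no peak to a feature) are replaced by
#' half the smallest observed area of that feature, the usual stand-in for
#' values below the detection limit. Features observed nowhere become 0.
#'
#' @param table a [feature_table].
#' @return the table with no missing values.
#' @export
impute_halfmin <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  for (i in seq_len(nrow(v))) {
    na <- is.na(v[i, ])
    if (any(na)) {
      obs <- v[i, !na]
      v[i, na] <- if (length(obs)) min(obs) / 2 else 0
    }
  }
  feature_table(v, table$features)
}

#' Read and write feature tables, peak lists and manifests
#'
#' Plain-CSV serialization. A feature-table CSV holds `feature_id`, `rt`,
#' `mz`, `sn`, `n_detected`, then one column per sample. A peak-list CSV
#' holds one ion observation per row (`scan_rt_min`, `mz`, `intensity`);
#' a manifest CSV holds `sample_id`, `class`, `run_type`,
#' `injection_order` and optionally `batch`.
#'
#' @param table a [feature_table].
#' @param path file path.
#' @return `read_feature_table` returns a [feature_table];
#'   `write_feature_table` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- cbind(table$features, as.data.frame(table$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_cols <- intersect(c("feature_id", "rt", "mz", "sn", "n_detected"),
                         names(df))
  sample_cols <- setdiff(names(df), meta_cols)
  feature_table(as.matrix(df[, sample_cols, drop = FALSE]),
                df[, meta_cols, drop = FALSE])
}

#' @rdname write_feature_table
#' @param run a peak-list data frame (`scan_rt_min`, `mz`, `intensity`).
#' @param run_id,run_type metadata attached to the returned run.
#' @export
write_peaklist_run <- function(run, path) {
  utils::write.csv(run[, c("scan_rt_min", "mz", "intensity")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_peaklist_run <- function(path, run_id = basename(path),
                              run_type = "study") {
  run <- utils::read.csv(path)
  stop_if(!all(c("scan_rt_min", "mz", "intensity") %in% names(run)),
          "peak-list CSV needs columns scan_rt_min, mz, intensity")
  attr(run, "run_id") <- run_id
  attr(run, "run_type") <- run_type
  run
}

#' @rdname write_feature_table
#' @param manifest a sample manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(!all(c("sample_id", "class", "run_type") %in% names(m)),
          "manifest CSV needs columns sample_id, class, run_type")
  stop_if(!all(m$run_type %in% c("study", "qc", "blank")),
          "run_type must be one of study, qc, blank")
  m
}

#' Read a centroided mzML run as a peak list
#'
#' Thin reader over the `mzR` backend: all MS1 centroids of the file are
#' flattened to one ion observation per row. Retention times are converted
#' from seconds to minutes.
#'
#' @param path mzML file.
#' @inheritParams read_peaklist_run
#' @return a peak-list data frame as from [read_peaklist_run()].
#' @export
read_mzml_run <- function(path, run_id = basename(path),
                          run_type = "study") {
  stop_if(!requireNamespace("mzR", quietly = TRUE),
          "reading mzML requires the 'mzR' package")
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hd <- mzR::header(ms)
  hd <- hd[hd$msLevel == 1L, , drop = FALSE]
  pk <- mzR::peaks(ms, hd$seqNum)
  if (is.matrix(pk)) pk <- list(pk)
  run <- do.call(rbind, lapply(seq_along(pk), function(i) {
    data.frame(scan_rt_min = hd$retentionTime[i] / 60,
               mz = pk[[i]][, 1], intensity = pk[[i]][, 2])
  }))
  attr(run, "run_id") <- run_id
  attr(run, "run_type") <- run_type
  run
}
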