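#' Coefficient of variation
#'
#' `100 * sd / mean` of a set of peak areas. Undefined (returned as `NA`)
#' when the mean is zero or not finite.
#'
#' @param values numeric vector of at least 2 areas.
#' @return percent CV, or `NA_real_` when undefined.
#' @export
compute_cv <- function(values) {
  values <- values[!is.na(values)]
  stop_if(length(values) < 2, "CV needs at least 2 values")
  m <- mean(values)
  if (!is.finite(m) || m == 0) return(NA_real_)
  100 * stats::sd(values) / m
}

#' Inter- and intra-assay CV report from QC injections
#'
#' For every feature, the intra-assay CV is the worst (largest) CV over
#' repeated QC injections of one pool arm within one batch, and the
#' inter-assay CV is the worst CV over all of one arm's QC injections
#' across the whole sequence. The two QC pool arms (cancer pool, benign
#' pool) are evaluated separately and the maximum is reported, the
#' conservative reading when a single CV threshold is applied downstream.
#'
#' @param table a [feature_table] (raw or normalized areas).
#' @param manifest sample manifest; QC rows are `run_type == "qc"`, their
#'   `class` names the pool arm, and `batch` (if present) drives the
#'   intra-assay grouping.
#' @return data frame `feature_id`, `intra_cv`, `inter_cv`, `cv_max`
#'   (percent; `NA` where undefined).
#' @export
qc_cv_report <- function(table, manifest) {
  stopifnot(inherits(table, "feature_table"))
  qc <- manifest[manifest$run_type == "qc", , drop = FALSE]
  stop_if(nrow(qc) < 2, "CV report needs at least 2 QC injections")
  if (is.null(qc$batch)) qc$batch <- 1L
  v <- table$values[, qc$sample_id, drop = FALSE]
  worst <- function(groups) {
    cvs <- vapply(groups, function(cols) {
      if (length(cols) < 2) return(rep(NA_real_, nrow(v)))
      apply(v[, cols, drop = FALSE], 1, function(x) {
        x <- x[!is.na(x)]
        if (length(x) < 2) NA_real_ else {
          m <- mean(x)
          if (!is.finite(m) || m == 0) NA_real_ else 100 * stats::sd(x) / m
        }
      })
    }, numeric(nrow(v)))
    if (is.null(dim(cvs))) cvs <- matrix(cvs, nrow = nrow(v))
    out <- apply(cvs, 1, function(x) if (all(is.na(x))) NA_real_
                 else max(x, na.rm = TRUE))
    out
  }
  inter <- worst(split(qc$sample_id, qc$class))
  intra <- worst(split(qc$sample_id, interaction(qc$class, qc$batch,
                                                 drop = TRUE)))
  cv_max <- pmax(intra, inter)
  cv_max[is.na(intra) & is.na(inter)] <- NA_real_
  cv_max[is.na(intra) & !is.na(inter)] <- inter[is.na(intra) & !is.na(inter)]
  cv_max[!is.na(intra) & is.na(inter)] <- intra[!is.na(intra) & is.na(inter)]
  data.frame(feature_id = table$features$feature_id,
             intra_cv = intra, inter_cv = inter, cv_max = cv_max,
             stringsAsFactors = FALSE)
}

#' QC-ratio normalization
#'
#' Every cell is replaced by the ratio of its peak area to the feature's
#' average area over the QC injections; QC columns are retained with their
#' own ratios (per-feature QC mean becomes 1 by construction). Features
#' whose QC mean is zero, missing or undefined cannot be normalized and
#' are removed from the returned table, with their ids reported, rather
#' than silently divided.
#'
#' @param table a [feature_table] of areas.
#' @param manifest sample manifest with `run_type`.
#' @return list with `table` (normalized [feature_table]), `flagged`
#'   (ids removed for undefined QC means) and `qc_mean` (named vector).
#' @export
normalize_to_qc <- function(table, manifest) {
  stopifnot(inherits(table, "feature_table"))
  qc_cols <- manifest$sample_id[manifest$run_type == "qc"]
  stop_if(length(qc_cols) < 1, "no QC samples present in the manifest")
  qc_mean <- rowMeans(table$values[, qc_cols, drop = FALSE], na.rm = TRUE)
  flagged <- table$features$feature_id[!is.finite(qc_mean) | qc_mean <= 0]
  keep <- setdiff(table$features$feature_id, flagged)
  out <- ft_subset(table, keep)
  out$values <- out$values / qc_mean[keep]
  list(table = out, flagged = flagged, qc_mean = qc_mean)
}
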