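#' Feature filter cascade
#'
#' Four-stage feature selection applied to an aligned (and normalized)
#' feature table, in order: blank comparison, QC CV, signal-to-noise, and
#' isotope/adduct/in-source-fragment deduplication. Each stage is also
#' available on its own. [run_filter_cascade()] applies them in sequence
#' and returns a fully accounted `filter_report`.
#'
#' @name featfilter
NULL

feature_means <- function(table, cols) {
  m <- rowMeans(table$values[, cols, drop = FALSE], na.rm = TRUE)
  m[!is.finite(m)] <- 0
  m
}

#' @describeIn featfilter remove features not sufficiently above blanks:
#'   a feature is removed when its mean study area is below `min_ratio`
#'   times its mean blank area. Errors when the manifest holds no blank
#'   runs (skip the stage explicitly via the `stages` argument of
#'   [run_filter_cascade()] instead).
#' @param table a [feature_table].
#' @param manifest sample manifest.
#' @param min_ratio required study-to-blank mean ratio (default 5).
#' @return each `filter_*` returns `list(table, removed)`.
#' @export
filter_blank <- function(table, manifest, min_ratio = 5) {
  stopifnot(inherits(table, "feature_table"))
  blanks <- manifest$sample_id[manifest$run_type == "blank"]
  stop_if(length(blanks) == 0,
          "no blank runs in the manifest; drop \"blank\" from the cascade ",
          "stages to skip this filter explicitly")
  study <- manifest$sample_id[manifest$run_type == "study"]
  removed <- table$features$feature_id[
    feature_means(table, study) < min_ratio * feature_means(table, blanks)]
  list(table = ft_subset(table, removed, drop = TRUE), removed = removed)
}

#' @describeIn featfilter remove features whose QC CV exceeds `max_cv`
#'   percent (strictly "more than"; a CV of exactly `max_cv` is retained).
#'   Features with an undefined CV are removed conservatively.
#' @param cv_report output of [qc_cv_report()]; must cover every feature.
#' @param max_cv CV threshold in percent (default 50).
#' @export
filter_cv <- function(table, cv_report, max_cv = 50) {
  stopifnot(inherits(table, "feature_table"))
  idx <- match(table$features$feature_id, cv_report$feature_id)
  stop_if(anyNA(idx), "cv_report does not cover all features")
  cv <- cv_report$cv_max[idx]
  removed <- table$features$feature_id[is.na(cv) | cv > max_cv]
  list(table = ft_subset(table, removed, drop = TRUE), removed = removed)
}

#' @describeIn featfilter remove small features whose representative
#'   signal-to-noise (the median over contributing peaks, stored on the
#'   table) is strictly below `min_sn`. An infinite S/N (zero noise
#'   estimate) is always retained.
#' @param min_sn signal-to-noise threshold (default 100).
#' @export
filter_sn <- function(table, min_sn = 100) {
  stopifnot(inherits(table, "feature_table"))
  sn <- table$features$sn
  stop_if(is.null(sn), "feature table carries no signal-to-noise column")
  removed <- table$features$feature_id[!is.na(sn) & sn < min_sn]
  list(table = ft_subset(table, removed, drop = TRUE), removed = removed)
}

#' @describeIn featfilter delete isotope, adduct and in-source fragment
#'   ions. A feature is removed as an isotope when a more intense feature
#'   co-elutes (|dRT| <= `sat_rt_tol`) one isotope spacing below it
#'   (m/z - 1.0033/z, z in `charges`, within `sat_mz_tol`); as an adduct
#'   when a more intense co-eluting feature sits one adduct mass below
#'   (negative-mode deltas: formate +46.0055, Na-H +21.9819, Cl +34.9689);
#'   and as an in-source fragment when a more intense co-eluting feature
#'   of higher m/z has an across-sample area profile correlating at
#'   Pearson r >= `frag_cor` with it. Flags are evaluated simultaneously
#'   on the incoming table and removed together.
#' @param sat_rt_tol co-elution tolerance in minutes (default 0.1).
#' @param sat_mz_tol satellite mass-match tolerance in Da (default 0.01).
#' @param charges charge states considered for isotope spacing.
#' @param adduct_deltas named vector of adduct mass offsets (Da).
#' @param frag_cor correlation threshold for the fragment rule.
#' @param intensity_cols columns used for mean intensity and correlation
#'   profiles; defaults to all columns (pass the study samples when a
#'   manifest is at hand).
#' @param intensity optional named vector (`feature_id ->` mean raw area)
#'   used for the "more intense" comparisons. Required in spirit whenever
#'   the table holds QC-normalized ratios, whose per-feature means are ~1
#'   by construction and carry no intensity information.
#' @export
filter_satellites <- function(table, sat_rt_tol = 0.1, sat_mz_tol = 0.01,
                              charges = c(1L, 2L),
                              adduct_deltas = ADDUCT_DELTAS,
                              frag_cor = 0.95,
                              intensity_cols = NULL,
                              intensity = NULL) {
  stopifnot(inherits(table, "feature_table"))
  cols <- intensity_cols %||% colnames(table$values)
  v <- table$values[, cols, drop = FALSE]
  inten <- if (!is.null(intensity)) {
    unname(intensity[table$features$feature_id])
  } else rowMeans(v, na.rm = TRUE)
  inten[!is.finite(inten)] <- 0
  rt <- table$features$rt; mz <- table$features$mz
  n <- length(rt)
  ord <- order(rt)
  reason <- rep(NA_character_, n)
  iso_d <- ISOTOPE_SPACING / charges
  for (oi in seq_len(n)) {
    f <- ord[oi]
    # co-eluting window around f in RT order
    lo <- oi; while (lo > 1 && rt[ord[lo - 1]] >= rt[f] - sat_rt_tol) lo <- lo - 1
    hi <- oi; while (hi < n && rt[ord[hi + 1]] <= rt[f] + sat_rt_tol) hi <- hi + 1
    cand <- ord[lo:hi]
    cand <- cand[cand != f & inten[cand] > inten[f]]
    if (!length(cand)) next
    dmz <- mz[f] - mz[cand]
    if (any(abs(outer(dmz, iso_d, `-`)) <= sat_mz_tol)) {
      reason[f] <- "isotope"; next
    }
    if (any(abs(outer(dmz, unname(adduct_deltas), `-`)) <= sat_mz_tol)) {
      reason[f] <- "adduct"; next
    }
    higher <- cand[mz[cand] > mz[f]]
    for (g in higher) {
      r <- suppressWarnings(stats::cor(v[f, ], v[g, ],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && r >= frag_cor) { reason[f] <- "fragment"; break }
    }
  }
  removed <- table$features$feature_id[!is.na(reason)]
  list(table = ft_subset(table, removed, drop = TRUE), removed = removed,
       reason = stats::setNames(reason[!is.na(reason)], removed))
}

#' Run the four-stage filter cascade
#'
#' Applies blank comparison, CV, signal-to-noise and satellite removal in
#' that order and accounts for every feature: the report's stage-wise
#' counts satisfy `n_out[k] == n_in[k+1]` and removals plus survivors sum
#' to the initial feature count.
#'
#' @param table a [feature_table] (normalized areas).
#' @param manifest sample manifest.
#' @param cv_report a [qc_cv_report()]; computed from `table` when `NULL`.
#' @param min_ratio,max_cv,min_sn,sat_rt_tol,sat_mz_tol,charges,adduct_deltas,frag_cor
#'   stage parameters, see the individual filters.
#' @param stages character subset of
#'   `c("blank", "cv", "sn", "satellite")`, in cascade order; stages can
#'   be skipped explicitly (e.g. when no blanks were acquired).
#' @param raw_intensity named vector of mean raw areas per feature for
#'   the satellite stage's intensity comparisons; supply it whenever
#'   `table` holds QC-normalized ratios (defaults to study-column means
#'   of `table`, appropriate only for unnormalized areas).
#' @return list with `table` (surviving features) and `report`
#'   (a `filter_report`: per-stage accounting plus a removal audit).
#' @export
run_filter_cascade <- function(table, manifest, cv_report = NULL,
                               min_ratio = 5, max_cv = 50, min_sn = 100,
                               sat_rt_tol = 0.1, sat_mz_tol = 0.01,
                               charges = c(1L, 2L),
                               adduct_deltas = ADDUCT_DELTAS,
                               frag_cor = 0.95,
                               stages = c("blank", "cv", "sn", "satellite"),
                               raw_intensity = NULL) {
  stopifnot(inherits(table, "feature_table"))
  stages <- match.arg(stages, c("blank", "cv", "sn", "satellite"),
                      several.ok = TRUE)
  if (is.null(cv_report) && "cv" %in% stages)
    cv_report <- qc_cv_report(table, manifest)
  study <- manifest$sample_id[manifest$run_type == "study"]
  n0 <- nrow(table$values)
  report <- data.frame(stage = character(0), n_in = integer(0),
                       n_removed = integer(0), n_out = integer(0))
  audit <- data.frame(feature_id = character(0), stage = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
  for (st in stages) {
    n_in <- nrow(table$values)
    res <- switch(st,
      blank = filter_blank(table, manifest, min_ratio),
      cv = filter_cv(table, cv_report, max_cv),
      sn = filter_sn(table, min_sn),
      satellite = filter_satellites(table, sat_rt_tol, sat_mz_tol, charges,
                                    adduct_deltas, frag_cor,
                                    intensity_cols = intersect(
                                      study, colnames(table$values)),
                                    intensity = raw_intensity))
    table <- res$table
    reason <- if (st == "satellite") unname(res$reason[res$removed])
    else rep(st, length(res$removed))
    if (length(res$removed))
      audit <- rbind(audit, data.frame(feature_id = res$removed, stage = st,
                                       reason = reason,
                                       stringsAsFactors = FALSE))
    report <- rbind(report, data.frame(
      stage = st, n_in = n_in, n_removed = length(res$removed),
      n_out = nrow(table$values)))
  }
  rep_obj <- structure(list(report = report, audit = audit,
                            n_initial = n0,
                            kept = table$features$feature_id),
                       class = "filter_report")
  list(table = table, report = rep_obj)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Feature filter cascade:\n")
  counts <- c(x$n_initial, x$report$n_out)
  cat("  ", paste(counts, collapse = " -> "), "features\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
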