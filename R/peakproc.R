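#' Extract ion chromatograms from a centroided run
#'
#' Groups the run's ion observations along m/z by single-linkage gap
#' clustering: the sorted ion m/z values are split wherever the gap to the
#' next ion exceeds `mz_gap`. Every ion lands in exactly one trace. Each
#' trace lives on the run's full scan grid with zero fill; per-scan m/z is
#' the intensity-weighted mean of the member ions in that scan.
#'
#' @param run a peak-list data frame (`scan_rt_min`, `mz`, `intensity`).
#' @param mz_gap m/z split gap in Da; kept well below the 0.06 Da
#'   cross-run alignment tolerance.
#' @param scan_times optional explicit scan grid; defaults to the sorted
#'   unique retention times observed in the run.
#' @return list of `eic_trace` objects (fields `rt`, `intensity`, `mz`
#'   per scan, `mz_center`).
#' @export
extract_eics <- function(run, mz_gap = 0.02, scan_times = NULL) {
  stop_if(is.null(run) || nrow(run) == 0, "empty run: no ion observations")
  grid <- scan_times %||% sort(unique(run$scan_rt_min))
  stop_if(length(grid) < 2, "run must span at least 2 scans")
  ord <- order(run$mz)
  mz <- run$mz[ord]
  grp <- cumsum(c(1, diff(mz) > mz_gap))
  idx_scan <- findInterval(run$scan_rt_min[ord], grid)
  n <- length(grid)
  lapply(split(seq_along(ord), grp), function(i) {
    inten <- numeric(n)
    mz_w <- numeric(n)
    ii <- idx_scan[i]
    inten_i <- run$intensity[ord][i]
    for (k in seq_along(i)) {
      inten[ii[k]] <- inten[ii[k]] + inten_i[k]
      mz_w[ii[k]] <- mz_w[ii[k]] + inten_i[k] * mz[i[k]]
    }
    mz_scan <- ifelse(inten > 0, mz_w / inten, NA_real_)
    structure(list(rt = grid, intensity = inten, mz = mz_scan,
                   mz_center = sum(inten_i * mz[i]) / sum(inten_i)),
              class = "eic_trace")
  })
}

#' Savitzky-Golay smoothing of an ion chromatogram
#'
#' Least-squares local-polynomial smoothing; reproduces constants and
#' straight lines exactly (up to edge handling) and suppresses
#' high-frequency noise before differentiation. Negative smoothed
#' intensities are clipped at zero.
#'
#' @param trace an `eic_trace`.
#' @param window odd filter length (points).
#' @param polyorder polynomial order, `< window`.
#' @return the smoothed trace.
#' @export
smooth_trace <- function(trace, window = 7L, polyorder = 2L) {
  stopifnot(inherits(trace, "eic_trace"))
  stop_if(window %% 2 == 0, "window must be odd")
  stop_if(polyorder >= window, "polyorder must be smaller than window")
  stop_if(window > length(trace$intensity),
          "window larger than the trace (", length(trace$intensity), " points)")
  trace$intensity <- pmax(0, signal::sgolayfilt(trace$intensity,
                                                p = polyorder, n = window))
  trace
}

# derivative sign-change walk shared by detect_peaks and the fast per-run
# path; returns index triples plus areas as plain vectors
detect_core <- function(t, y, zero_eps) {
  n <- length(y)
  none <- list(i_start = integer(0), i_apex = integer(0),
               i_end = integer(0), area = numeric(0))
  if (n < 3 || all(y == 0)) return(none)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1] <- d[2]; d[n] <- d[n - 1]
  eps <- zero_eps * max(abs(d))
  s <- sign(d) * (abs(d) >= eps)

  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  i_start <- i_apex <- i_end <- integer(0)
  area <- numeric(0)
  j <- 1L
  while (j <= m) {
    if (r$values[j] == 1 && j > 1L) {
      a_start <- starts[j] - 1L               # last point before the rise
      k <- j + 1L
      while (k <= m && r$values[k] != -1) k <- k + 1L
      if (k <= m) {                           # found the falling flank
        l <- k + 1L                           # first run after the fall
        if (l <= m) {
          a_end <- starts[l]
          a_apex <- a_start - 1L + which.max(y[a_start:a_end])
          if (t[a_start] < t[a_apex] && t[a_apex] < t[a_end] &&
              y[a_apex] > 0) {
            span <- a_start:a_end
            ar <- sum(diff(t[span]) *
                        (y[span][-1] + y[span][-length(span)]) / 2)
            if (ar > 0) {
              i_start <- c(i_start, a_start); i_apex <- c(i_apex, a_apex)
              i_end <- c(i_end, a_end); area <- c(area, ar)
            }
          }
          # a valley (-1 directly followed by +1) re-opens at the same scan
          j <- if (r$values[l] == 1) l - 1L else l
        } else j <- m + 1L                    # still falling at trace end
      } else j <- m + 1L                      # never fell: no apex
    }
    j <- j + 1L
  }
  list(i_start = i_start, i_apex = i_apex, i_end = i_end, area = area)
}

# per-peak weighted m/z and trace-level robust noise; vector results
peak_annotate <- function(y, mz_scan, mz_center, core) {
  np <- length(core$i_start)
  mz_pk <- numeric(np)
  in_peak <- rep(FALSE, length(y))
  for (k in seq_len(np)) {
    span <- core$i_start[k]:core$i_end[k]
    in_peak[span] <- TRUE
    w <- y[span]
    mzv <- mz_scan[span]
    ok <- !is.na(mzv) & w > 0
    mz_pk[k] <- if (any(ok)) sum(w[ok] * mzv[ok]) / sum(w[ok]) else mz_center
  }
  resid <- y[!in_peak]
  noise <- if (length(resid) >= 3) stats::mad(resid) else 0
  height <- y[core$i_apex]
  list(mz = mz_pk, height = height,
       sn = if (noise > 0) height / noise else rep(Inf, np))
}

#' Detect chromatographic peaks on a smoothed trace
#'
#' The trace is differentiated (central differences on the smoothed
#' signal); a peak starts where the derivative crosses from zero to
#' positive, tops where it turns from positive to negative, and ends where
#' it returns from negative to zero. "Zero" means `|d| < zero_eps *
#' max|d|`, which makes the crossings robust on floating-point grids.
#' Incomplete start/apex/end triples at the trace edges are discarded.
#' The area is the trapezoidal integral from start to end; a valley where
#' the derivative flips directly from negative to positive closes one peak
#' and opens the next at the same scan.
#'
#' Signal-to-noise is the peak height over a robust noise scale:
#' `1.4826 * MAD` of the trace outside all detected peak spans. A zero
#' noise estimate yields `S/N = Inf`.
#'
#' @param trace a smoothed `eic_trace`.
#' @param zero_eps relative derivative threshold treated as zero.
#' @param run_id identifier copied into the output rows.
#' @return data frame with columns `run_id`, `rt_start`, `rt_apex`,
#'   `rt_end`, `mz`, `height`, `area`, `sn` (0 rows when nothing found).
#' @export
detect_peaks <- function(trace, zero_eps = 1e-3, run_id = NA_character_) {
  stopifnot(inherits(trace, "eic_trace"))
  core <- detect_core(trace$rt, trace$intensity, zero_eps)
  if (!length(core$i_start))
    return(data.frame(run_id = character(0), rt_start = numeric(0),
                      rt_apex = numeric(0), rt_end = numeric(0),
                      mz = numeric(0), height = numeric(0),
                      area = numeric(0), sn = numeric(0)))
  ann <- peak_annotate(trace$intensity, trace$mz, trace$mz_center, core)
  data.frame(run_id = run_id, rt_start = trace$rt[core$i_start],
             rt_apex = trace$rt[core$i_apex], rt_end = trace$rt[core$i_end],
             mz = ann$mz, height = ann$height, area = core$area,
             sn = ann$sn)
}

#' Detect all peaks of one run
#'
#' Convenience wrapper: extracts ion chromatograms, smooths each and runs
#' peak detection, returning one combined peak table for the run.
#'
#' @inheritParams extract_eics
#' @inheritParams smooth_trace
#' @inheritParams detect_peaks
#' @param min_height discard peaks below this apex height (counts); weeds
#'   out single-ion noise spikes before alignment.
#' @return a per-run peak data frame (see [detect_peaks()]).
#' @export
detect_run_peaks <- function(run, mz_gap = 0.02, window = 7L,
                             polyorder = 2L, zero_eps = 1e-3,
                             min_height = 0) {
  run_id <- attr(run, "run_id") %||% NA_character_
  traces <- extract_eics(run, mz_gap = mz_gap)
  filt <- signal::sgolay(p = polyorder, n = window)
  acc <- vector("list", length(traces))
  for (ti in seq_along(traces)) {
    tr <- traces[[ti]]
    if (length(tr$intensity) < window) next
    y <- pmax(0, signal::sgolayfilt(tr$intensity, filt))
    core <- detect_core(tr$rt, y, zero_eps)
    if (!length(core$i_start)) next
    ann <- peak_annotate(y, tr$mz, tr$mz_center, core)
    acc[[ti]] <- list(rt_start = tr$rt[core$i_start],
                      rt_apex = tr$rt[core$i_apex],
                      rt_end = tr$rt[core$i_end],
                      mz = ann$mz, height = ann$height, area = core$area,
                      sn = ann$sn)
  }
  acc <- acc[!vapply(acc, is.null, TRUE)]
  pull <- function(f) unlist(lapply(acc, `[[`, f), use.names = FALSE)
  out <- data.frame(run_id = if (length(acc)) run_id else character(0),
                    rt_start = pull("rt_start"), rt_apex = pull("rt_apex"),
                    rt_end = pull("rt_end"), mz = pull("mz"),
                    height = pull("height"), area = pull("area"),
                    sn = pull("sn"))
  out <- out[out$height >= min_height, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit an affine retention-time and m/z drift model from internal standards
#'
#' Matches the run's detected peaks to internal-standard reference
#' coordinates (highest peak within the matching tolerances wins) and fits
#' `reference = offset + slope * observed` by least squares, separately for
#' retention time and m/z.
#'
#' @param run_peaks peak data frame of one run.
#' @param references data frame of reference coordinates (`rt`, `mz`).
#' @param match_rt_tol,match_mz_tol matching tolerances.
#' @return a `drift_model` (fields `rt_offset`, `rt_slope`, `mz_offset`,
#'   `mz_slope`, `n_matched`).
#' @export
fit_drift <- function(run_peaks, references,
                      match_rt_tol = 0.3, match_mz_tol = 0.06) {
  obs_rt <- numeric(0); obs_mz <- numeric(0)
  ref_rt <- numeric(0); ref_mz <- numeric(0)
  for (i in seq_len(nrow(references))) {
    cand <- which(abs(run_peaks$rt_apex - references$rt[i]) <= match_rt_tol &
                    abs(run_peaks$mz - references$mz[i]) <= match_mz_tol)
    if (!length(cand)) next
    best <- cand[which.max(run_peaks$height[cand])]
    obs_rt <- c(obs_rt, run_peaks$rt_apex[best])
    obs_mz <- c(obs_mz, run_peaks$mz[best])
    ref_rt <- c(ref_rt, references$rt[i])
    ref_mz <- c(ref_mz, references$mz[i])
  }
  stop_if(length(obs_rt) < 2,
          "drift fit needs >= 2 matched internal standards (run ",
          run_peaks$run_id[1] %||% "?", " matched ", length(obs_rt), ")")
  affine <- function(obs, ref) {
    if (stats::var(obs) < 1e-12) c(offset = mean(ref - obs), slope = 1)
    else {
      b <- stats::cov(obs, ref) / stats::var(obs)
      c(offset = mean(ref) - b * mean(obs), slope = b)
    }
  }
  a_rt <- affine(obs_rt, ref_rt)
  a_mz <- affine(obs_mz, ref_mz)
  structure(list(rt_offset = unname(a_rt[1]), rt_slope = unname(a_rt[2]),
                 mz_offset = unname(a_mz[1]), mz_slope = unname(a_mz[2]),
                 n_matched = length(obs_rt)),
            class = "drift_model")
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf("Drift model (%d standards): rt' = %+0.4f + %.5f rt,  mz' = %+0.4f + %.6f mz\n",
              x$n_matched, x$rt_offset, x$rt_slope, x$mz_offset, x$mz_slope))
  invisible(x)
}

#' Apply a drift model to peak coordinates
#'
#' Coordinate-only transform: retention times (start/apex/end) and m/z are
#' corrected, areas and heights are untouched.
#'
#' @param peaks a peak data frame.
#' @param model a `drift_model` from [fit_drift()].
#' @return the corrected peak data frame.
#' @export
apply_drift <- function(peaks, model) {
  stopifnot(inherits(model, "drift_model"))
  for (col in c("rt_start", "rt_apex", "rt_end"))
    peaks[[col]] <- model$rt_offset + model$rt_slope * peaks[[col]]
  peaks$mz <- model$mz_offset + model$mz_slope * peaks$mz
  peaks
}

#' Align peaks across runs into a feature table
#'
#' Pools all runs' drift-corrected peaks, orders them canonically by
#' descending height (ties by retention time, m/z, run id) and greedily
#' clusters: each peak joins the nearest existing cluster whose centroid is
#' within `rt_tol` and `mz_tol` and which does not yet hold a peak of the
#' same run; otherwise it seeds a new cluster. The canonical ordering makes
#' the result independent of the order the runs are supplied in. Cluster
#' centroids are running means of member coordinates; cell values are peak
#' areas, missing where a run contributed none; the feature's
#' signal-to-noise is the median over members.
#'
#' @param per_run_peaks named list of per-run peak data frames (names are
#'   the sample ids and define the column order), or a single combined
#'   data frame with a `run_id` column.
#' @param rt_tol,mz_tol alignment tolerances (defaults 0.3 min, 0.06 Da).
#' @return a [feature_table].
#' @export
align_runs <- function(per_run_peaks, rt_tol = 0.3, mz_tol = 0.06) {
  stop_if(rt_tol <= 0 || mz_tol <= 0, "tolerances must be strictly positive")
  if (is.data.frame(per_run_peaks)) {
    pool <- per_run_peaks
    run_ids <- unique(pool$run_id)
  } else {
    pool <- do.call(rbind, per_run_peaks)
    run_ids <- names(per_run_peaks)
  }
  stop_if(is.null(pool) || nrow(pool) == 0, "no peaks to align")
  ord <- order(-pool$height, pool$rt_apex, pool$mz, pool$run_id)
  pool <- pool[ord, , drop = FALSE]
  np <- nrow(pool)

  # clusters, bucketed by integer m/z bucket for fast neighbour lookup
  c_rt <- numeric(np); c_mz <- numeric(np); c_n <- integer(np)
  members <- vector("list", np)
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  n_cl <- 0L
  bucket_of <- function(mz) as.character(floor(mz / mz_tol))
  for (i in seq_len(np)) {
    rt <- pool$rt_apex[i]; mz <- pool$mz[i]; run <- pool$run_id[i]
    b <- floor(mz / mz_tol)
    cand <- unlist(lapply(as.character((b - 1L):(b + 1L)), function(k)
      if (exists(k, envir = buckets, inherits = FALSE))
        get(k, envir = buckets) else NULL))
    chosen <- 0L
    if (length(cand)) {
      ok <- cand[abs(c_rt[cand] - rt) <= rt_tol &
                   abs(c_mz[cand] - mz) <= mz_tol]
      if (length(ok)) {
        # nearest centroid first; skip clusters already holding this run
        dist <- sqrt(((c_rt[ok] - rt) / rt_tol)^2 +
                       ((c_mz[ok] - mz) / mz_tol)^2)
        for (cl in ok[order(dist)]) {
          if (!run %in% pool$run_id[members[[cl]]]) { chosen <- cl; break }
        }
      }
    }
    if (chosen == 0L) {
      n_cl <- n_cl + 1L
      chosen <- n_cl
      c_rt[chosen] <- rt; c_mz[chosen] <- mz; c_n[chosen] <- 1L
      members[[chosen]] <- i
      key <- bucket_of(mz)
      prev <- if (exists(key, envir = buckets, inherits = FALSE))
        get(key, envir = buckets) else integer(0)
      assign(key, c(prev, chosen), envir = buckets)
    } else {
      old_key <- bucket_of(c_mz[chosen])
      k <- c_n[chosen]
      c_rt[chosen] <- (c_rt[chosen] * k + rt) / (k + 1)
      c_mz[chosen] <- (c_mz[chosen] * k + mz) / (k + 1)
      c_n[chosen] <- k + 1L
      members[[chosen]] <- c(members[[chosen]], i)
      new_key <- bucket_of(c_mz[chosen])
      if (new_key != old_key) {
        assign(old_key, setdiff(get(old_key, envir = buckets), chosen),
               envir = buckets)
        prev <- if (exists(new_key, envir = buckets, inherits = FALSE))
          get(new_key, envir = buckets) else integer(0)
        assign(new_key, c(prev, chosen), envir = buckets)
      }
    }
  }

  keep <- seq_len(n_cl)
  feat_ord <- keep[order(c_rt[keep], c_mz[keep])]
  values <- matrix(NA_real_, length(feat_ord), length(run_ids),
                   dimnames = list(NULL, run_ids))
  sn <- numeric(length(feat_ord)); ndet <- integer(length(feat_ord))
  for (fi in seq_along(feat_ord)) {
    mem <- members[[feat_ord[fi]]]
    values[fi, pool$run_id[mem]] <- pool$area[mem]
    sn[fi] <- stats::median(pool$sn[mem])
    ndet[fi] <- length(mem)
  }
  feats <- data.frame(
    feature_id = sprintf("F%05d", seq_along(feat_ord)),
    rt = c_rt[feat_ord], mz = c_mz[feat_ord], sn = sn, n_detected = ndet,
    stringsAsFactors = FALSE)
  feature_table(values, feats)
}
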