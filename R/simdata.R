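#' @section Satellite masses:
#' Isotope satellites sit at parent m/z + 1.0033/z; adducts at the
#' negative-mode deltas for formate (+46.0055), sodium minus proton
#' (+21.9819) and chloride (+34.9689); in-source fragments at a lower m/z
#' with an area profile tightly proportional to the parent's.
#' @keywords internal
#' @name simdata-internals
NULL

ISOTOPE_SPACING <- 1.0033
ADDUCT_DELTAS <- c(formate = 46.00548, sodium = 21.98194, chloride = 34.96885)

# ---- cohort skeleton ------------------------------------------------------

# Features, per-sample true areas, manifest and measured-area matrix.
# All randomness is drawn here so the fast and raw paths share one truth.
sim_skeleton <- function(cfg) {
  n_study <- cfg$n_cancer + cfg$n_control
  study_ids <- c(sprintf("CA%02d", seq_len(cfg$n_cancer)),
                 sprintf("CT%02d", seq_len(cfg$n_control)))
  study_class <- rep(c("cancer", "control"), c(cfg$n_cancer, cfg$n_control))

  # internal standards: fixed anchors spanning the RT range
  n_is <- cfg$n_internal_standards
  is_rt <- seq(cfg$rt_range[1] + 0.4, cfg$rt_range[2] - 0.4, length.out = n_is)
  is_mz <- seq(cfg$mz_range[1] + 60, cfg$mz_range[2] - 60, length.out = n_is)

  feat <- data.frame(
    feature_id = sprintf("IS%02d", seq_len(n_is)),
    rt = is_rt, mz = is_mz,
    role = "internal_standard", parent_id = NA_character_,
    differential = FALSE, lfc = 0, z = 1L,
    base_area = rep(8e5, n_is), rel = 1,
    stringsAsFactors = FALSE)

  mono <- data.frame(
    feature_id = sprintf("GP%04d", seq_len(cfg$n_features)),
    rt = stats::runif(cfg$n_features, cfg$rt_range[1], cfg$rt_range[2]),
    mz = stats::runif(cfg$n_features, cfg$mz_range[1], cfg$mz_range[2]),
    role = "monoisotopic", parent_id = NA_character_,
    differential = FALSE, lfc = 0, z = 1L,
    base_area = stats::rlnorm(cfg$n_features, cfg$base_area_meanlog,
                              cfg$base_area_sdlog),
    rel = 1, stringsAsFactors = FALSE)
  n_diff <- round(cfg$frac_differential * cfg$n_features)
  if (n_diff > 0) {
    idx <- sample.int(cfg$n_features, n_diff)
    mag <- abs(stats::rnorm(n_diff, cfg$effect_log2fc, cfg$effect_log2fc / 4))
    mono$differential[idx] <- TRUE
    mono$lfc[idx] <- mag * sample(c(-1, 1), n_diff, replace = TRUE)
  }

  sat <- lapply(c("isotope", "adduct", "fragment"), function(role) {
    p <- switch(role, isotope = cfg$isotope_prob, adduct = cfg$adduct_prob,
                fragment = cfg$fragment_prob)
    has <- stats::runif(cfg$n_features) < p
    if (!any(has)) return(NULL)
    par <- mono[has, , drop = FALSE]
    k <- nrow(par)
    z <- sample(cfg$charge_states, k, replace = TRUE)
    dmz <- switch(role,
      isotope = ISOTOPE_SPACING / z,
      adduct = unname(ADDUCT_DELTAS[sample.int(length(ADDUCT_DELTAS), k,
                                               replace = TRUE)]),
      fragment = -pmin(stats::runif(k, 100, 400), par$mz - 160))
    data.frame(
      feature_id = sprintf("%s_%s", toupper(substr(role, 1, 2)),
                           par$feature_id),
      rt = par$rt, mz = par$mz + dmz,
      role = role, parent_id = par$feature_id,
      differential = FALSE, lfc = 0, z = z,
      base_area = par$base_area, rel = stats::runif(k, 0.15, 0.55),
      stringsAsFactors = FALSE)
  })
  feat <- rbind(feat, mono, do.call(rbind, sat))
  rownames(feat) <- feat$feature_id
  n_feat <- nrow(feat)

  # true per-study-sample areas (biological variation; satellites track parent)
  class_mult <- outer(feat$lfc, ifelse(study_class == "cancer", 0.5, -0.5),
                      function(l, s) 2 ^ (l * s))
  bio <- matrix(exp(stats::rnorm(n_feat * n_study, 0, cfg$biological_cv)),
                n_feat, n_study)
  bio[feat$role == "internal_standard", ] <- 1
  truth_area <- feat$base_area * class_mult * bio
  parent_row <- match(feat$parent_id, feat$feature_id)
  is_sat <- !is.na(parent_row)
  if (any(is_sat)) {
    track <- matrix(exp(stats::rnorm(sum(is_sat) * n_study, 0, 0.02)),
                    sum(is_sat), n_study)
    truth_area[is_sat, ] <- truth_area[parent_row[is_sat], ] *
      feat$rel[is_sat] * track
  }
  dimnames(truth_area) <- list(feat$feature_id, study_ids)

  # QC pools: mean of n_qc_pool random study sera per arm
  pool_of <- function(ids) {
    take <- sample(ids, min(cfg$n_qc_pool, length(ids)))
    rowMeans(truth_area[, take, drop = FALSE])
  }
  qc_pool <- cbind(cancer = pool_of(study_ids[study_class == "cancer"]),
                   control = pool_of(study_ids[study_class == "control"]))

  # injection sequence: blanks first, then randomized study order with a QC
  # after every qc_interval study injections, alternating pool arms
  study_order <- sample(study_ids)
  inj_id <- character(0); inj_type <- character(0); inj_class <- character(0)
  if (cfg$n_blanks > 0) {
    inj_id <- sprintf("BL%02d", seq_len(cfg$n_blanks))
    inj_type <- rep("blank", cfg$n_blanks)
    inj_class <- rep("blank", cfg$n_blanks)
  }
  qc_n <- 0L
  for (i in seq_along(study_order)) {
    inj_id <- c(inj_id, study_order[i])
    inj_type <- c(inj_type, "study")
    inj_class <- c(inj_class,
                   study_class[match(study_order[i], study_ids)])
    if (i %% cfg$qc_interval == 0) {
      qc_n <- qc_n + 1L
      arm <- if (qc_n %% 2L == 1L) "control" else "cancer"
      inj_id <- c(inj_id, sprintf("QC%02d", qc_n))
      inj_type <- c(inj_type, "qc")
      inj_class <- c(inj_class, paste0("qc_", arm))
    }
  }
  n_inj <- length(inj_id)
  manifest <- data.frame(
    sample_id = inj_id, class = inj_class, run_type = inj_type,
    injection_order = seq_len(n_inj),
    batch = as.integer(cut(seq_len(n_inj), cfg$n_batches, labels = FALSE)),
    stringsAsFactors = FALSE)

  # expected (noise-free) area of every feature in every injection
  expected <- matrix(0, n_feat, n_inj,
                     dimnames = list(feat$feature_id, inj_id))
  is_row <- feat$role == "internal_standard"
  for (j in seq_len(n_inj)) {
    expected[, j] <- switch(manifest$run_type[j],
      study = truth_area[, inj_id[j]],
      qc = qc_pool[, sub("qc_", "", manifest$class[j])],
      blank = ifelse(is_row, feat$base_area, 0))
  }

  # measured areas: fresh multiplicative measurement noise per injection;
  # satellite ions arise from the parent's ion current in the same
  # injection, so their measured areas track the parent's measured area
  # (tight multiplicative scatter) rather than drawing independent noise
  measured <- expected *
    matrix(exp(stats::rnorm(n_feat * n_inj, 0, cfg$noise_sd_rel)),
           n_feat, n_inj)
  if (any(is_sat)) {
    sat_rows <- which(is_sat)
    measured[sat_rows, ] <- measured[parent_row[sat_rows], , drop = FALSE] *
      feat$rel[sat_rows] *
      matrix(exp(stats::rnorm(length(sat_rows) * n_inj, 0, 0.02)),
             length(sat_rows), n_inj)
  }
  measured[expected == 0] <- 0

  truth <- structure(list(
    features = feat[, c("feature_id", "rt", "mz", "role", "parent_id",
                        "differential", "lfc", "z")],
    areas = truth_area, qc_pool = qc_pool, config = cfg),
    class = "cohort_truth")
  list(features = feat, manifest = manifest, measured = measured,
       truth = truth)
}

#' @export
print.cohort_truth <- function(x, ...) {
  tab <- table(x$features$role)
  cat("Synthetic cohort ground truth:",
      nrow(x$features), "features,",
      ncol(x$areas), "study samples\n")
  print(tab)
  cat(sprintf("differential monoisotopic features: %d\n",
              sum(x$features$differential)))
  invisible(x)
}

# ---- fast path ------------------------------------------------------------

#' Generate an ideal aligned feature table with ground truth
#'
#' Fast path that bypasses raw-run rendering and peak extraction: the
#' returned table has the statistical structure the raw-run path would
#' yield after ideal peak extraction and alignment (consensus coordinates
#' carry small jitter; per-feature signal-to-noise values are drawn rather
#' than estimated from traces). Intended for exercising the filter cascade,
#' multivariate modelling and differential statistics in isolation.
#'
#' @param config a [cohort_config()].
#' @return a list with elements `table` (a [feature_table]), `manifest`
#'   (sample manifest data frame) and `truth` (a `cohort_truth`).
#' @export
simulate_feature_table <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    sk <- sim_skeleton(config)
    n_feat <- nrow(sk$features)
    values <- sk$measured
    if (config$sample_scale_sd > 0) {
      sc <- exp(stats::rnorm(ncol(values), 0, config$sample_scale_sd))
      values <- sweep(values, 2, sc, `*`)
    }
    feats <- data.frame(
      feature_id = sk$features$feature_id,
      rt = sk$features$rt + stats::rnorm(n_feat, 0, config$rt_jitter_sd / 2),
      mz = sk$features$mz + stats::rnorm(n_feat, 0, config$mz_jitter_sd / 2),
      sn = stats::rlnorm(n_feat, config$sn_meanlog, config$sn_sdlog),
      n_detected = ncol(values),
      stringsAsFactors = FALSE)
    feats$sn[sk$features$role == "internal_standard"] <- Inf
    tab <- feature_table(values, feats)
    list(table = tab, manifest = sk$manifest, truth = sk$truth)
  })
}

# ---- raw-run path ---------------------------------------------------------

#' Generate a synthetic cohort of centroided LC-MS runs
#'
#' Renders every injection of a simulated two-class serum glycopeptide
#' cohort as a centroided peak list (retention time in minutes, m/z in Da,
#' intensity in counts). Study runs are interleaved with pooled-QC runs
#' after every `qc_interval` study injections; blank runs contain only
#' noise ions and the internal-standard anchors. Each run carries its own
#' affine retention-time and m/z drift plus per-peak jitter, and all
#' intensities carry multiplicative measurement noise.
#'
#' @param config a [cohort_config()].
#' @return a list with elements `runs` (named list of peak-list data frames
#'   with columns `scan_rt_min`, `mz`, `intensity` and attributes `run_id`,
#'   `run_type`), `manifest`, `truth`, and `references` (the
#'   internal-standard reference coordinates used for drift correction).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    sk <- sim_skeleton(config)
    feat <- sk$features
    manifest <- sk$manifest
    n_inj <- nrow(manifest)
    grid <- seq(config$rt_range[1] - 0.5, config$rt_range[2] + 0.5,
                by = config$scan_step)
    sigma <- config$peak_sigma_rt
    run_scale <- exp(stats::rnorm(n_inj, 0, config$run_scale_sd))
    rt_off <- stats::rnorm(n_inj, 0, config$rt_drift_sd)
    rt_slo <- 1 + stats::rnorm(n_inj, 0, config$rt_slope_sd)
    mz_off <- stats::rnorm(n_inj, 0, config$mz_drift_sd)
    mz_slo <- 1 + stats::rnorm(n_inj, 0, config$mz_slope_sd)

    runs <- vector("list", n_inj)
    names(runs) <- manifest$sample_id
    for (j in seq_len(n_inj)) {
      areas <- sk$measured[, j] * run_scale[j]
      present <- which(areas > 0)
      apex <- rt_off[j] + rt_slo[j] * feat$rt[present] +
        stats::rnorm(length(present), 0, config$rt_jitter_sd)
      mzc <- mz_off[j] + mz_slo[j] * feat$mz[present] +
        stats::rnorm(length(present), 0, config$mz_jitter_sd)
      parts <- vector("list", length(present))
      for (i in seq_along(present)) {
        h <- areas[present[i]] / (sigma * sqrt(2 * pi))
        lo <- findInterval(apex[i] - 4.5 * sigma, grid) + 1L
        hi <- findInterval(apex[i] + 4.5 * sigma, grid)
        if (hi < lo) next
        t <- grid[lo:hi]
        y <- h * exp(-(t - apex[i])^2 / (2 * sigma^2))
        if (config$point_noise_rel > 0)
          y <- y * exp(stats::rnorm(length(y), 0, config$point_noise_rel))
        keep <- y > h * 1e-4
        if (!any(keep)) next
        parts[[i]] <- data.frame(
          scan_rt_min = t[keep],
          mz = mzc[i] + stats::rnorm(sum(keep), 0, 5e-4),
          intensity = y[keep])
      }
      if (config$noise_ions_per_run > 0) {
        k <- config$noise_ions_per_run
        parts[[length(parts) + 1L]] <- data.frame(
          scan_rt_min = sample(grid, k, replace = TRUE),
          mz = stats::runif(k, config$mz_range[1], config$mz_range[2]),
          intensity = stats::rlnorm(k, log(config$noise_intensity_mean), 1))
      }
      run <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
      run <- run[order(run$scan_rt_min, run$mz), , drop = FALSE]
      rownames(run) <- NULL
      attr(run, "run_id") <- manifest$sample_id[j]
      attr(run, "run_type") <- manifest$run_type[j]
      runs[[j]] <- run
    }
    refs <- feat[feat$role == "internal_standard", c("feature_id", "rt", "mz")]
    rownames(refs) <- NULL
    list(runs = runs, manifest = manifest, truth = sk$truth,
         references = refs)
  })
}
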