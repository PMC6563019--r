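#' Configuration for a synthetic serum glycopeptide cohort
#'
#' Collects every tunable of the synthetic-cohort generator. Defaults emulate
#' a two-class serum glycopeptide study: 39 cancer and 45 non-cancer sera,
#' a pooled-QC injection after every 10 study samples, a handful of blank
#' injections, fetuin-like internal-standard anchor peaks, and
#' isotope/adduct/in-source-fragment satellites around each true
#' glycopeptide feature.
#'
#' @param n_cancer,n_control study group sizes.
#' @param n_features number of true (monoisotopic) glycopeptide features.
#' @param frac_differential fraction of features whose group means differ.
#' @param effect_log2fc mean absolute log2 fold change of differential
#'   features; per-feature magnitudes are drawn from
#'   `Normal(effect_log2fc, effect_log2fc/4)` truncated at zero, with a
#'   random sign.
#' @param rt_range,mz_range elution window (minutes) and mass window (Da).
#' @param peak_sigma_rt Gaussian chromatographic peak width (sd, minutes).
#' @param biological_cv between-subject variation of true feature areas
#'   within a class (sd on the natural-log scale).
#' @param noise_sd_rel multiplicative measurement noise applied to every
#'   injection (sd on the natural-log scale); this alone drives QC
#'   replicate scatter, so assay CVs are a function of it.
#' @param rt_drift_sd,mz_drift_sd per-run drift offsets (sd); must stay
#'   inside half the alignment tolerances (0.3 min, 0.06 Da) so that
#'   ground-truth matching is well defined.
#' @param rt_slope_sd,mz_slope_sd per-run drift slope scatter around 1.
#' @param rt_jitter_sd,mz_jitter_sd per-peak positional jitter (sd).
#' @param qc_interval a pooled-QC injection after every `qc_interval` study
#'   samples (alternating cancer-pool and benign-pool QCs).
#' @param n_qc_pool sera pooled into each QC pool.
#' @param n_blanks blank injections (noise and internal standards only).
#' @param n_batches contiguous injection batches; drives the intra- vs
#'   inter-assay CV distinction.
#' @param isotope_prob,adduct_prob,fragment_prob probability that a feature
#'   carries the corresponding satellite ion.
#' @param n_internal_standards fixed internal-standard anchors spanning the
#'   retention-time range, present in every run including blanks.
#' @param base_area_meanlog,base_area_sdlog log-normal base peak areas.
#' @param run_scale_sd per-run injection-efficiency scatter (log sd); only
#'   applied when raw runs are rendered.
#' @param scan_step scan spacing of the rendered runs (minutes).
#' @param noise_ions_per_run random noise ions added to each rendered run.
#' @param noise_intensity_mean mean intensity of noise ions (counts).
#' @param point_noise_rel per-scan intensity scatter within a rendered peak.
#' @param charge_states charge states available to isotope satellites.
#' @param sn_meanlog,sn_sdlog log-normal draw for per-feature
#'   signal-to-noise in the fast (table-level) generator, where no trace
#'   exists to estimate it from.
#' @param sample_scale_sd per-sample scale factor scatter in the fast
#'   generator (log sd); defaults to 0 because injection-level scale
#'   variation is an acquisition phenomenon modelled in the raw-run path.
#' @param seed integer seed; identical configurations produce identical
#'   cohorts.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_feature_table()]
#' @export
cohort_config <- function(n_cancer = 39L, n_control = 45L,
                          n_features = 300L,
                          frac_differential = 0.1,
                          effect_log2fc = 1,
                          rt_range = c(1, 14),
                          mz_range = c(800, 2500),
                          peak_sigma_rt = 0.05,
                          biological_cv = 0.3,
                          noise_sd_rel = 0.1,
                          rt_drift_sd = 0.05,
                          mz_drift_sd = 0.01,
                          rt_slope_sd = 0.002,
                          mz_slope_sd = 4e-6,
                          rt_jitter_sd = 0.01,
                          mz_jitter_sd = 0.002,
                          qc_interval = 10L,
                          n_qc_pool = 10L,
                          n_blanks = 3L,
                          n_batches = 3L,
                          isotope_prob = 0.3,
                          adduct_prob = 0.15,
                          fragment_prob = 0.1,
                          n_internal_standards = 5L,
                          base_area_meanlog = log(2e5),
                          base_area_sdlog = 1,
                          run_scale_sd = 0.1,
                          scan_step = 0.01,
                          noise_ions_per_run = 200L,
                          noise_intensity_mean = 50,
                          point_noise_rel = 0.02,
                          charge_states = 1L,
                          sn_meanlog = log(400),
                          sn_sdlog = 0.8,
                          sample_scale_sd = 0,
                          seed = 1L) {
  cfg <- as.list(environment())
  stop_if(!is_count(n_cancer) || !is_count(n_control) || n_cancer < 1 ||
            n_control < 1, "n_cancer and n_control must be positive counts")
  stop_if(!is_count(n_features) || n_features < 1, "n_features must be >= 1")
  for (f in c("frac_differential", "isotope_prob", "adduct_prob",
              "fragment_prob"))
    stop_if(!is_fraction(cfg[[f]]), sprintf("%s must be a fraction in [0,1]", f))
  stop_if(!is_range(rt_range), "rt_range must be an increasing [lo, hi] pair")
  stop_if(!is_range(mz_range), "mz_range must be an increasing [lo, hi] pair")
  stop_if(effect_log2fc < 0, "effect_log2fc must be non-negative")
  stop_if(peak_sigma_rt <= 0, "peak_sigma_rt must be positive")
  stop_if(rt_drift_sd < 0 || rt_drift_sd >= 0.3 / 2,
          "rt_drift_sd must lie in [0, 0.15): drift must stay inside half ",
          "the 0.3 min alignment tolerance")
  stop_if(mz_drift_sd < 0 || mz_drift_sd >= 0.06 / 2,
          "mz_drift_sd must lie in [0, 0.03): drift must stay inside half ",
          "the 0.06 Da alignment tolerance")
  stop_if(!is_count(qc_interval) || qc_interval < 1,
          "qc_interval must be a positive count")
  stop_if(!is_count(n_blanks), "n_blanks must be a count")
  stop_if(!is_count(n_batches) || n_batches < 1, "n_batches must be >= 1")
  stop_if(!is_count(n_internal_standards) || n_internal_standards < 2,
          "need at least 2 internal standards to fit an affine drift model")
  stop_if(any(c(biological_cv, noise_sd_rel, run_scale_sd, sample_scale_sd,
                rt_jitter_sd, mz_jitter_sd) < 0),
          "noise and jitter parameters must be non-negative")
  stop_if(!all(charge_states %in% 1:3), "charge_states must be within 1..3")
  stop_if(!is_count(abs(seed)), "seed must be an integer")
  cfg$n_cancer <- as.integer(n_cancer)
  cfg$n_control <- as.integer(n_control)
  cfg$n_features <- as.integer(n_features)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  study samples : %d cancer / %d control\n",
              x$n_cancer, x$n_control))
  cat(sprintf("  features      : %d monoisotopic (%.0f%% differential, |log2FC| ~ %.2f)\n",
              x$n_features, 100 * x$frac_differential, x$effect_log2fc))
  cat(sprintf("  satellites    : isotope %.2f / adduct %.2f / fragment %.2f\n",
              x$isotope_prob, x$adduct_prob, x$fragment_prob))
  cat(sprintf("  QC every %d study injections, %d blanks, %d batches, seed %d\n",
              x$qc_interval, x$n_blanks, x$n_batches, x$seed))
  invisible(x)
}
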