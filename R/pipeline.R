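#' Pipeline configuration
#'
#' Bundles every tunable of the full pipeline with its validated default:
#' alignment tolerances (0.3 min / 0.06 Da), smoothing window, filter
#' thresholds (blank ratio 5, CV 50 percent, S/N 100, satellite tolerances),
#' model settings (orthogonal components, 7 folds, 0.8 training
#' fraction) and the volcano/heat-map parameters. Unknown keys are
#' rejected, and a configuration round-trips losslessly through its YAML
#' on-disk form.
#'
#' @param cohort a [cohort_config()] describing the simulated cohort
#'   (ignored when `input_dir` points at acquired peak-list CSV runs).
#' @param out_dir artifact directory.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param input_dir optional directory of acquired runs (peak-list CSV
#'   named `<sample_id>.csv` plus `manifest.csv` and `references.csv`);
#'   `NULL` simulates from `cohort`.
#' @param eic,smoothing,alignment,filters,model,diffstats stage parameter
#'   lists; see Defaults in the function signature.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            out_dir = tempfile("glycopipe_run_"),
                            seed = 1L,
                            input_dir = NULL,
                            eic = list(mz_gap = 0.02),
                            smoothing = list(window = 7L, polyorder = 2L),
                            alignment = list(rt_tol = 0.3, mz_tol = 0.06,
                                             zero_eps = 1e-3,
                                             min_height = 0),
                            filters = list(min_ratio = 5, max_cv = 50,
                                           min_sn = 100, sat_rt_tol = 0.1,
                                           sat_mz_tol = 0.01,
                                           frag_cor = 0.95,
                                           stages = c("blank", "cv", "sn",
                                                      "satellite")),
                            model = list(n_ortho = 1L, k = 7L,
                                         train_fraction = 0.8,
                                         case_class = "cancer",
                                         control_class = "control"),
                            diffstats = list(n_top = 300L)) {
  defaults <- list(
    eic = list(mz_gap = 0.02),
    smoothing = list(window = 7L, polyorder = 2L),
    alignment = list(rt_tol = 0.3, mz_tol = 0.06, zero_eps = 1e-3,
                     min_height = 0),
    filters = list(min_ratio = 5, max_cv = 50, min_sn = 100,
                   sat_rt_tol = 0.1, sat_mz_tol = 0.01, frag_cor = 0.95,
                   stages = c("blank", "cv", "sn", "satellite")),
    model = list(n_ortho = 1L, k = 7L, train_fraction = 0.8,
                 case_class = "cancer", control_class = "control"),
    diffstats = list(n_top = 300L))
  merge_block <- function(name, given) {
    unknown <- setdiff(names(given), names(defaults[[name]]))
    stop_if(length(unknown) > 0, "unknown ", name, " key(s): ",
            paste(unknown, collapse = ", "))
    utils::modifyList(defaults[[name]], given)
  }
  cfg <- list(cohort = cohort, out_dir = out_dir, seed = as.integer(seed),
              input_dir = input_dir,
              eic = merge_block("eic", eic),
              smoothing = merge_block("smoothing", smoothing),
              alignment = merge_block("alignment", alignment),
              filters = merge_block("filters", filters),
              model = merge_block("model", model),
              diffstats = merge_block("diffstats", diffstats))
  stop_if(!inherits(cohort, "cohort_config") && is.null(input_dir),
          "cohort must be a cohort_config when no input_dir is given")
  structure(cfg, class = "pipeline_config")
}

#' Write or read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a validated
#'   [pipeline_config()]; the writer returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- unclass(config)
  plain$cohort <- if (is.null(plain$cohort)) NULL else unclass(plain$cohort)
  yaml::write_yaml(plain, path, precision = 15L)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("cohort", "out_dir", "seed", "input_dir", "eic", "smoothing",
             "alignment", "filters", "model", "diffstats")
  unknown <- setdiff(names(raw), known)
  stop_if(length(unknown) > 0, "unknown pipeline config key(s): ",
          paste(unknown, collapse = ", "))
  cohort <- if (!is.null(raw$cohort)) {
    extra <- setdiff(names(raw$cohort), names(formals(cohort_config)))
    stop_if(length(extra) > 0, "unknown cohort key(s): ",
            paste(extra, collapse = ", "))
    do.call(cohort_config, raw$cohort)
  } else cohort_config()
  pipeline_config(cohort = cohort, out_dir = raw$out_dir %||% tempfile(),
                  seed = raw$seed %||% 1L, input_dir = raw$input_dir,
                  eic = raw$eic %||% list(),
                  smoothing = raw$smoothing %||% list(),
                  alignment = raw$alignment %||% list(),
                  filters = raw$filters %||% list(),
                  model = raw$model %||% list(),
                  diffstats = raw$diffstats %||% list())
}

#' Run the full pipeline
#'
#' Composes every stage: cohort simulation (or reading acquired runs),
#' per-run peak detection, internal-standard drift correction, cross-run
#' alignment, QC-ratio normalization with CV reporting, the four-stage
#' filter cascade, missing-value imputation, a stratified train/test
#' split, PCA and OPLS-DA modelling with test-set prediction, volcano
#' statistics and the heat-map ratio matrix. All artifacts are written
#' under `config$out_dir` as CSV/JSON, together with a run manifest
#' recording the resolved configuration hash, master seed, stage timings
#' and package version. Identical configurations (including seeds)
#' reproduce identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return (invisibly) a list with the in-memory stage results:
#'   `manifest`, `peaks`, `table` (aligned), `normalized`, `cv_report`,
#'   `filter_report`, `filtered`, `split`, `pca`, `model`,
#'   `test_prediction`, `volcano`, `heatmap`, `truth` (simulated runs
#'   only), `run_info`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(...)
  t0 <- tic()

  # ---- input: simulate or read -------------------------------------------
  if (is.null(config$input_dir)) {
    say("simulating cohort")
    sim <- simulate_cohort(config$cohort)
    runs <- sim$runs; manifest <- sim$manifest
    references <- sim$references; truth <- sim$truth
  } else {
    manifest <- read_manifest(file.path(config$input_dir, "manifest.csv"))
    references <- utils::read.csv(file.path(config$input_dir,
                                            "references.csv"))
    runs <- lapply(seq_len(nrow(manifest)), function(i)
      read_peaklist_run(file.path(config$input_dir,
                                  paste0(manifest$sample_id[i], ".csv")),
                        run_id = manifest$sample_id[i],
                        run_type = manifest$run_type[i]))
    names(runs) <- manifest$sample_id
    truth <- NULL
  }
  write_manifest(manifest, file.path(config$out_dir, "manifest.csv"))
  timings["input"] <- tic() - t0; t0 <- tic()

  # ---- detection + drift correction --------------------------------------
  say("detecting peaks in ", length(runs), " runs")
  peaks <- lapply(runs, function(run) {
    pk <- detect_run_peaks(run, mz_gap = config$eic$mz_gap,
                           window = config$smoothing$window,
                           polyorder = config$smoothing$polyorder,
                           zero_eps = config$alignment$zero_eps,
                           min_height = config$alignment$min_height)
    if (nrow(pk) < 2) return(pk)
    model <- tryCatch(fit_drift(pk, references), error = function(e) NULL)
    if (is.null(model)) pk else apply_drift(pk, model)
  })
  all_peaks <- do.call(rbind, peaks)
  utils::write.csv(all_peaks, file.path(config$out_dir, "peaks.csv"),
                   row.names = FALSE)
  timings["detect"] <- tic() - t0; t0 <- tic()

  # ---- alignment ----------------------------------------------------------
  say("aligning")
  table <- align_runs(peaks, rt_tol = config$alignment$rt_tol,
                      mz_tol = config$alignment$mz_tol)
  write_feature_table(table, file.path(config$out_dir, "feature_table.csv"))
  timings["align"] <- tic() - t0; t0 <- tic()

  # ---- QC normalization + CV ---------------------------------------------
  cv_report <- qc_cv_report(table, manifest)
  utils::write.csv(cv_report, file.path(config$out_dir, "cv_report.csv"),
                   row.names = FALSE)
  norm <- normalize_to_qc(table, manifest)
  write_feature_table(norm$table,
                      file.path(config$out_dir, "feature_table_normalized.csv"))
  timings["normalize"] <- tic() - t0; t0 <- tic()

  # ---- filter cascade -----------------------------------------------------
  say("filter cascade")
  study_cols <- manifest$sample_id[manifest$run_type == "study"]
  raw_int <- rowMeans(table$values[, study_cols, drop = FALSE], na.rm = TRUE)
  fc <- run_filter_cascade(norm$table, manifest, cv_report,
                           raw_intensity = raw_int,
                           min_ratio = config$filters$min_ratio,
                           max_cv = config$filters$max_cv,
                           min_sn = config$filters$min_sn,
                           sat_rt_tol = config$filters$sat_rt_tol,
                           sat_mz_tol = config$filters$sat_mz_tol,
                           frag_cor = config$filters$frag_cor,
                           stages = config$filters$stages)
  utils::write.csv(fc$report$report,
                   file.path(config$out_dir, "filter_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_initial = fc$report$n_initial, stages = fc$report$report,
         kept = fc$report$kept),
    file.path(config$out_dir, "filter_report.json"),
    auto_unbox = TRUE, digits = NA)
  utils::write.csv(fc$report$audit,
                   file.path(config$out_dir, "removed_features.csv"),
                   row.names = FALSE)
  timings["filter"] <- tic() - t0; t0 <- tic()

  # ---- modelling ----------------------------------------------------------
  say("modelling")
  filled <- impute_halfmin(fc$table)
  study <- manifest[manifest$run_type == "study", ]
  x <- t(filled$values[, study$sample_id, drop = FALSE])
  classes <- stats::setNames(study$class, study$sample_id)
  split <- make_split(classes, fraction = config$model$train_fraction,
                      seed = derive_seed(config$seed, 11L))
  pca <- pca_fit(uv_scale(x)$x, n_components = 2)
  model <- oplsda(x[split$train, , drop = FALSE], classes[split$train],
                  n_ortho = config$model$n_ortho, k = config$model$k,
                  seed = derive_seed(config$seed, 23L))
  pred_test <- predict(model, x[split$test, , drop = FALSE])
  pred_train <- predict(model, x[split$train, , drop = FALSE])
  scores <- rbind(
    data.frame(sample_id = split$train, class = unname(classes[split$train]),
               set = "train", pred_train[, c("t_pred", "y_hat", "class")
                                         [c(1, 2, 3)]],
               row.names = NULL),
    data.frame(sample_id = split$test, class = unname(classes[split$test]),
               set = "test", pred_test[, c("t_pred", "y_hat", "class")],
               row.names = NULL))
  names(scores)[names(scores) == "class.1"] <- "class_call"
  utils::write.csv(scores, file.path(config$out_dir, "oplsda_scores.csv"),
                   row.names = FALSE)
  model_json <- list(
    levels = model$levels, n_ortho = model$n_ortho,
    R2X = model$R2X, R2Y = model$R2Y, Q2cum = model$Q2cum,
    y_loading = model$y_loading, y_mean = model$y_mean,
    weights = as.numeric(model$weights),
    ortho_weights = unname(as.matrix(model$ortho_weights)),
    scaling = list(center = as.numeric(model$scaling$center),
                   scale = as.numeric(model$scaling$scale),
                   features = model$scaling$kept),
    seed = config$seed)
  jsonlite::write_json(model_json,
                       file.path(config$out_dir, "oplsda_model.json"),
                       auto_unbox = TRUE, digits = NA)
  if (model$n_ortho > 0) {
    el <- tryCatch(hotelling_ellipse(cbind(model$scores,
                                           model$ortho_scores[, 1])),
                   error = function(e) NULL)
    if (!is.null(el))
      utils::write.csv(data.frame(
        center_x = el$center[1], center_y = el$center[2],
        semi_major = el$semi_axes[1], semi_minor = el$semi_axes[2],
        angle_rad = el$angle, alpha = el$alpha),
        file.path(config$out_dir, "hotelling_ellipse.csv"),
        row.names = FALSE)
  }
  timings["model"] <- tic() - t0; t0 <- tic()

  # ---- differential statistics -------------------------------------------
  say("differential statistics")
  vol <- volcano_stats(filled, classes, case = config$model$case_class,
                       control = config$model$control_class)
  utils::write.csv(vol, file.path(config$out_dir, "volcano.csv"),
                   row.names = FALSE)
  n_top <- min(config$diffstats$n_top, nrow(vol))
  top <- select_top_features(vol, n_top)
  ctrl_ids <- names(classes)[classes == config$model$control_class]
  hm <- heatmap_ratio_matrix(filled, top, ctrl_ids,
                             sample_ids = names(classes)[order(classes)])
  utils::write.csv(cbind(feature_id = rownames(hm$ratio),
                         as.data.frame(hm$ratio)),
                   file.path(config$out_dir, "heatmap_ratio.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(feature_id = rownames(hm$bin),
                         as.data.frame(hm$bin)),
                   file.path(config$out_dir, "heatmap_bins.csv"),
                   row.names = FALSE)
  timings["diffstats"] <- tic() - t0

  # ---- run manifest --------------------------------------------------------
  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  run_info <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("glycopipe")),
    n_runs = nrow(manifest),
    n_features_aligned = nrow(table$values),
    n_features_final = nrow(fc$table$values),
    timings_sec = as.list(round(timings, 3)))
  jsonlite::write_json(run_info, file.path(config$out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(manifest = manifest, peaks = all_peaks, table = table,
                 normalized = norm, cv_report = cv_report,
                 filter_report = fc$report, filtered = fc$table,
                 split = split, pca = pca, model = model,
                 test_prediction = pred_test, volcano = vol, heatmap = hm,
                 truth = truth, run_info = run_info))
}
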