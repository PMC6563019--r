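# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately written without reference to the package
# internals it checks.

# textbook NIPALS PLS1: successive deflation of X and y
nipals_pls1 <- function(X, y, ncomp) {
  Xd <- X; yd <- y
  T_ <- NULL; q <- c()
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd)); w <- w / sqrt(sum(w^2))
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    qa <- sum(yd * t) / sum(t^2)
    Xd <- Xd - tcrossprod(t, p)
    yd <- yd - t * qa
    T_ <- cbind(T_, t); q <- c(q, qa)
  }
  list(scores = T_, yhat = drop(T_ %*% q))
}

# two-sample Welch t-test p-value by the textbook formulas
welch_p <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(tstat), df)
}

# a sampled Gaussian elution profile as an EIC trace
gaussian_trace <- function(height = 1000, sigma = 0.05, apex = 5,
                           from = 4, to = 6, step = 0.01, mz = 1000) {
  rt <- seq(from, to, by = step)
  y <- height * exp(-(rt - apex)^2 / (2 * sigma^2))
  structure(list(rt = rt, intensity = y, mz = rep(mz, length(rt)),
                 mz_center = mz), class = "eic_trace")
}

make_trace <- function(rt, intensity, mz = rep(1000, length(rt))) {
  structure(list(rt = rt, intensity = intensity, mz = mz,
                 mz_center = mean(mz)), class = "eic_trace")
}

# one-row peak table, for alignment tests
peak_row <- function(run_id, rt, mz, height = 1000, area = 100, sn = 500) {
  data.frame(run_id = run_id, rt_start = rt - 0.1, rt_apex = rt,
             rt_end = rt + 0.1, mz = mz, height = height, area = area,
             sn = sn)
}

# ten-feature cascade fixture with exact per-stage ground truth:
# blank removes F01 F02; CV removes F03 F04; S/N removes F05;
# satellite removes F06 F07 (isotopes of F09, F10) and F08 (formate
# adduct of F09); F09 F10 survive.  Expected counts 10 -> 8 -> 6 -> 5 -> 2.
cascade_fixture <- function() {
  study <- sprintf("S%d", 1:6)
  qcs <- sprintf("QC%d", 1:4)
  blanks <- c("B1", "B2")
  manifest <- data.frame(
    sample_id = c(study, qcs, blanks),
    class = c(rep(c("cancer", "control"), each = 3),
              rep("qc_pool", 4), rep("blank", 2)),
    run_type = c(rep("study", 6), rep("qc", 4), rep("blank", 2)),
    injection_order = 1:12, batch = 1L)
  ids <- sprintf("F%02d", 1:10)
  # per-feature: study level, QC values, blank level
  study_lvl <- c(100, 100, 500, 500, 500, 400, 300, 300, 1000, 1000)
  blank_lvl <- c(90, 50, 0, 0, 0, 0, 0, 0, 0, 0)
  qc_vals <- matrix(rep(c(100, 100, 100, 100), 10), 10, 4, byrow = TRUE)
  qc_vals[3, ] <- c(50, 150, 50, 150)   # CV 57.7%
  qc_vals[4, ] <- c(40, 160, 40, 160)   # CV 69.3%
  values <- cbind(matrix(rep(study_lvl, 6), 10, 6), qc_vals,
                  matrix(rep(blank_lvl, 2), 10, 2))
  colnames(values) <- manifest$sample_id
  feats <- data.frame(
    feature_id = ids,
    rt = c(1, 1.5, 2, 2.5, 3, 5.00, 7.00, 5.00, 5.00, 7.00),
    mz = c(300, 320, 340, 360, 380,
           1001.0033, 1201.0033, 1046.00548, 1000.00, 1200.00),
    sn = c(1000, 1000, 1000, 1000, 50, 1000, 1000, 1000, 1000, 1000),
    n_detected = 12L)
  list(table = feature_table(values, feats), manifest = manifest)
}

# compact feature-table cohorts for model-level tests
study_matrix <- function(sim) {
  study <- sim$manifest[sim$manifest$run_type == "study", ]
  list(x = t(sim$table$values[, study$sample_id, drop = FALSE]),
       classes = stats::setNames(study$class, study$sample_id))
}
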