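test_that("EIC extraction partitions ions and separates distinct m/z series", {
  run <- data.frame(
    scan_rt_min = rep(seq(1, 2, by = 0.1), 2),
    mz = rep(c(1000.0, 1000.5), each = 11),
    intensity = rep(c(500, 300), each = 11))
  attr(run, "run_id") <- "r1"
  traces <- extract_eics(run, mz_gap = 0.1)
  expect_length(traces, 2)
  expect_equal(unname(sort(vapply(traces, `[[`, 0, "mz_center"))),
               c(1000.0, 1000.5))
  # every ion assigned exactly once: total intensity conserved
  expect_equal(sum(vapply(traces, function(t) sum(t$intensity), 0)),
               sum(run$intensity))

  one <- extract_eics(run[run$mz == 1000, ], mz_gap = 0.1)
  expect_length(one, 1)
  expect_equal(one[[1]]$mz_center, 1000.0)
  expect_error(extract_eics(run[0, ]), "empty")
})

test_that("Savitzky-Golay smoothing reproduces constants and lines, shrinks noise", {
  rt <- seq(0, 1, by = 0.01)
  const <- make_trace(rt, rep(5, length(rt)))
  expect_equal(smooth_trace(const)$intensity, const$intensity)
  line <- make_trace(rt, 10 + 3 * rt)
  expect_equal(smooth_trace(line)$intensity, line$intensity,
               tolerance = 1e-10)
  # Monte-Carlo: smoothing a noisy Gaussian reduces residual sd
  set.seed(1)
  clean <- gaussian_trace()$intensity
  improv <- replicate(10, {
    noisy <- gaussian_trace()
    noise <- rnorm(length(clean), 0, 20)
    noisy$intensity <- pmax(0, clean + noise)
    sm <- smooth_trace(noisy, 7, 2)
    sd(sm$intensity - clean) < sd(noise)
  })
  expect_true(all(improv))
  expect_error(smooth_trace(const, window = 6), "odd")
  expect_error(smooth_trace(const, window = 3, polyorder = 3), "polyorder")
  expect_error(smooth_trace(make_trace(1:3 / 10, rep(1, 3)), window = 7),
               "larger than the trace")
})

test_that("derivative crossings bound a Gaussian peak; degenerate traces yield none", {
  tr <- smooth_trace(gaussian_trace(height = 1000, sigma = 0.05, apex = 5))
  pk <- detect_peaks(tr, run_id = "r")
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$rt_apex - 5), 0.0100001)
  expect_lt(pk$rt_start, pk$rt_apex)
  expect_gt(pk$rt_end, pk$rt_apex)
  expect_equal(pk$area, 1000 * 0.05 * sqrt(2 * pi), tolerance = 0.02)
  expect_equal(pk$mz, 1000)

  rt <- seq(0, 1, by = 0.01)
  expect_equal(nrow(detect_peaks(make_trace(rt, rep(0, length(rt))))), 0)
  expect_equal(nrow(detect_peaks(make_trace(rt, 1 + rt * 10))), 0)  # monotone
})

test_that("two resolved peaks split at the valley and re-detect identically", {
  rt <- seq(0, 3, by = 0.01)
  y <- 800 * exp(-(rt - 1)^2 / (2 * 0.05^2)) +
    600 * exp(-(rt - 2)^2 / (2 * 0.05^2))
  pk <- detect_peaks(smooth_trace(make_trace(rt, y)))
  expect_equal(nrow(pk), 2)
  expect_equal(pk$rt_apex, c(1, 2), tolerance = 0.011)
  # area additivity: detecting the two halves separately gives the same peaks
  left <- detect_peaks(smooth_trace(make_trace(rt[rt <= 1.5], y[rt <= 1.5])))
  right <- detect_peaks(smooth_trace(make_trace(rt[rt >= 1.5], y[rt >= 1.5])))
  both <- rbind(left, right)
  expect_equal(nrow(both), 2)
  # agreement up to the smoothing filter's edge handling at the cut point
  expect_equal(sort(both$area), sort(pk$area), tolerance = 1e-3)
})

test_that("drift fit recovers pure shifts and round-trips to identity", {
  refs <- data.frame(rt = c(2, 5, 8, 11), mz = c(900, 1200, 1500, 1800))
  peaks <- do.call(rbind, lapply(seq_len(nrow(refs)), function(i)
    peak_row("r1", refs$rt[i], refs$mz[i])))
  ident <- fit_drift(peaks, refs)
  expect_equal(ident$rt_offset, 0, tolerance = 1e-10)
  expect_equal(ident$rt_slope, 1, tolerance = 1e-10)
  expect_equal(apply_drift(peaks, ident), peaks, tolerance = 1e-12)

  shifted <- peaks
  shifted$rt_apex <- shifted$rt_apex + 0.10
  shifted$rt_start <- shifted$rt_start + 0.10
  shifted$rt_end <- shifted$rt_end + 0.10
  m <- fit_drift(shifted, refs)
  expect_equal(m$rt_offset, -0.10, tolerance = 1e-9)
  expect_equal(m$rt_slope, 1, tolerance = 1e-9)
  restored <- apply_drift(shifted, m)
  expect_equal(restored$rt_apex, peaks$rt_apex, tolerance = 1e-6)

  mz_shift <- peaks; mz_shift$mz <- mz_shift$mz + 0.02
  mm <- fit_drift(mz_shift, refs)
  expect_equal(mm$mz_offset, -0.02, tolerance = 1e-9)
  expect_error(fit_drift(peaks[1, ], refs), ">= 2 matched")
})

test_that("alignment honours the 0.3 min / 0.06 Da tolerance contract", {
  base <- function(rt2, mz2) list(
    r1 = peak_row("r1", 5.00, 1000.00),
    r2 = peak_row("r2", rt2, mz2))
  expect_equal(nrow(align_runs(base(5.29, 1000.05))$values), 1)  # inside both
  expect_equal(nrow(align_runs(base(5.31, 1000.00))$values), 2)  # RT outside
  expect_equal(nrow(align_runs(base(5.00, 1000.07))$values), 2)  # m/z outside
  expect_equal(nrow(align_runs(base(5.29, 1000.07))$values), 2)

  single <- align_runs(list(r1 = rbind(peak_row("r1", 3, 900),
                                       peak_row("r1", 6, 1100))))
  expect_equal(dim(single$values), c(2L, 1L))
  expect_true(all(!is.na(single$values)))
})

test_that("alignment is permutation-stable and one-peak-per-run", {
  set.seed(11)
  runs <- lapply(sprintf("r%d", 1:6), function(id) {
    do.call(rbind, lapply(1:15, function(i)
      peak_row(id, i + rnorm(1, 0, 0.03), 800 + 40 * i + rnorm(1, 0, 0.005),
               height = runif(1, 500, 2000))))
  })
  names(runs) <- sprintf("r%d", 1:6)
  a <- align_runs(runs)
  b <- align_runs(rev(runs))
  expect_equal(a$features$rt, b$features$rt)
  expect_equal(a$features$mz, b$features$mz)
  expect_equal(a$values[, colnames(a$values)], b$values[, colnames(a$values)])
  expect_equal(nrow(a$values), 15)
  expect_true(all(a$features$n_detected <= 6))
})

test_that("synthetic cohort: traces cover all features and recovery is one-to-one", {
  sim <- simulate_cohort(cohort_config(
    n_cancer = 3, n_control = 3, n_features = 60, qc_interval = 3,
    n_blanks = 1, noise_ions_per_run = 40, point_noise_rel = 0, seed = 5))
  run <- sim$runs[[which(sim$manifest$run_type == "study")[1]]]
  traces <- extract_eics(run)
  centers <- vapply(traces, `[[`, 0, "mz_center")
  tr <- sim$truth$features
  covered <- vapply(tr$mz, function(m) any(abs(centers - m) < 0.05), TRUE)
  expect_true(all(covered))

  peaks <- lapply(sim$runs, function(r) {
    pk <- detect_run_peaks(r)
    apply_drift(pk, fit_drift(pk, sim$references))
  })
  tab <- align_runs(peaks)
  mono <- tr[tr$role == "monoisotopic", ]
  n_match <- vapply(seq_len(nrow(mono)), function(i)
    sum(abs(tab$features$rt - mono$rt[i]) <= 0.15 &
          abs(tab$features$mz - mono$mz[i]) <= 0.03), 0L)
  expect_gte(mean(n_match == 1), 0.99)

  # drift correction reduces the median RT error against ground truth
  raw_peaks <- detect_run_peaks(sim$runs[[2]])
  corr <- apply_drift(raw_peaks, fit_drift(raw_peaks, sim$references))
  err <- function(pk) median(vapply(seq_len(nrow(mono)), function(i) {
    d <- abs(pk$rt_apex - mono$rt[i])
    min(d)
  }, 0))
  expect_lt(err(corr), err(raw_peaks))
})
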