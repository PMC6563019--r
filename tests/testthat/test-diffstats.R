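groups6 <- setNames(rep(c("case", "ctrl"), each = 4),
                    c(sprintf("a%d", 1:4), sprintf("b%d", 1:4)))

test_that("volcano reproduces the hand-computed Welch test and fold change", {
  v <- rbind(c(10, 12, 11, 13, 5, 6, 5, 6),
             c(7, 7.1, 6.9, 7, 7, 7.05, 6.95, 7))
  colnames(v) <- names(groups6)
  rownames(v) <- c("up", "flat")
  res <- volcano_stats(v, groups6, "case", "ctrl")
  expect_equal(res$mean_fold[1], 11.5 / 5.5, tolerance = 1e-12)
  expect_equal(res$mean_fold[1], 2.091, tolerance = 1e-3)
  # oracle: textbook Welch formulas, not the same code path
  expect_equal(res$p_value[1], welch_p(c(10, 12, 11, 13), c(5, 6, 5, 6)),
               tolerance = 1e-12)
  expect_true(res$significant[1])
  expect_false(res$significant[2])
  expect_equal(res$log2fc[1], log2(res$mean_fold[1]))
  expect_equal(res$minus_log10_p[1], -log10(res$p_value[1]))
})

test_that("significance gate: p and fold must both pass; identical groups never do", {
  # p below 0.05, fold 1.6 (> 1.5) -> significant
  v <- rbind(sig = c(16, 16.1, 15.9, 16, 10, 10.05, 9.95, 10))
  colnames(v) <- names(groups6)
  res <- volcano_stats(v, groups6, "case", "ctrl")
  expect_true(res$mean_fold[1] > 1.5 && res$p_value[1] < 0.05)
  expect_true(res$significant[1])
  # identical groups: fold 1, not significant
  same <- matrix(rep(c(3, 4, 5, 6), 2), 1, 8)
  colnames(same) <- names(groups6)
  r2 <- volcano_stats(same, groups6, "case", "ctrl")
  expect_equal(r2$mean_fold, 1)
  expect_false(r2$significant)
  # fold inside (0.7, 1.5) stays non-significant regardless of p
  shifted <- matrix(c(10, 10.01, 9.99, 10, 9, 9.01, 8.99, 9), 1, 8)
  colnames(shifted) <- names(groups6)
  r3 <- volcano_stats(shifted, groups6, "case", "ctrl")
  expect_lt(r3$p_value, 0.05)
  expect_false(r3$significant)
  # zero control mean flags the row instead of dividing
  zero <- matrix(c(5, 6, 5, 6, 0, 0, 0, 0), 1, 8)
  colnames(zero) <- names(groups6)
  r4 <- volcano_stats(zero, groups6, "case", "ctrl")
  expect_true(r4$flagged)
  expect_false(r4$significant)
})

test_that("top-feature selection orders by p then |log2 fold| then id", {
  vol <- data.frame(
    feature_id = c("A", "B", "C", "D"),
    p_value = c(0.01, 0.001, 0.01, 0.5),
    log2fc = c(2, 0.5, -3, 1))
  expect_equal(select_top_features(vol, 4), c("B", "C", "A", "D"))
  expect_equal(select_top_features(vol, 1), "B")
  expect_error(select_top_features(vol, 0), "positive")
  expect_error(select_top_features(vol, 5), "exceeds")
})

test_that("heat-map ratios: control rows average 1 and bins span <0.1 .. >10", {
  v <- rbind(f1 = c(12, 0.05, 1, 1, 1, 1),
             f2 = c(2, 0.5, 2, 0.5, 1.5, 0.5))
  colnames(v) <- c(sprintf("c%d", 1:2), sprintf("n%d", 1:4))
  ctrl <- sprintf("n%d", 1:4)
  hm <- heatmap_ratio_matrix(v, c("f1", "f2"), ctrl)
  expect_equal(unname(rowMeans(hm$ratio[, ctrl])), c(1, 1))
  expect_equal(unname(hm$bin["f1", "c1"]), 10L)  # ratio 12 -> top bin
  expect_equal(unname(hm$bin["f1", "c2"]), 0L)   # ratio 0.05 -> bottom bin
  expect_equal(unname(hm$bin["f1", "n1"]), 5L)   # at the control mean
  expect_length(hm$bin_labels, 11)
  # a zero-control-mean feature is dropped, not divided
  v2 <- rbind(v, f3 = c(1, 1, 0, 0, 0, 0))
  expect_message(hm2 <- heatmap_ratio_matrix(v2, c("f1", "f2", "f3"), ctrl),
                 "dropped")
  expect_equal(rownames(hm2$ratio), c("f1", "f2"))
})

test_that("heat-map case ratios average to the volcano fold (shared control mean)", {
  sim <- simulate_feature_table(cohort_config(
    n_features = 120, frac_differential = 0.3, isotope_prob = 0,
    adduct_prob = 0, fragment_prob = 0, seed = 19))
  st <- study_matrix(sim)
  v <- t(st$x)
  vol <- volcano_stats(v, st$classes, "cancer", "control")
  top <- select_top_features(vol, 30)
  ctrl <- names(st$classes)[st$classes == "control"]
  case <- names(st$classes)[st$classes == "cancer"]
  hm <- heatmap_ratio_matrix(v, top, ctrl)
  expect_equal(unname(rowMeans(hm$ratio[top, case])),
               vol$mean_fold[match(top, vol$feature_id)],
               tolerance = 1e-12)
})

test_that("null simulations hold the 5% rate and planted effects are detected", {
  rates <- vapply(1:3, function(s) {
    sim <- simulate_feature_table(cohort_config(
      n_features = 1500, frac_differential = 0, isotope_prob = 0,
      adduct_prob = 0, fragment_prob = 0, seed = s))
    st <- study_matrix(sim)
    vol <- volcano_stats(t(st$x), st$classes, "cancer", "control")
    keep <- !grepl("^IS", vol$feature_id)
    mean(vol$p_value[keep] < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.012)

  sim <- simulate_feature_table(cohort_config(
    n_features = 1000, frac_differential = 0.1, effect_log2fc = 1,
    isotope_prob = 0, adduct_prob = 0, fragment_prob = 0, seed = 77))
  st <- study_matrix(sim)
  vol <- volcano_stats(t(st$x), st$classes, "cancer", "control")
  diff_ids <- sim$truth$features$feature_id[sim$truth$features$differential]
  expect_gt(mean(vol$significant[match(diff_ids, vol$feature_id)]), 0.8)
})
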