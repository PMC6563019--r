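test_that("blank filter applies the mean-ratio rule with its boundary arithmetic", {
  fx <- cascade_fixture()
  manifest <- fx$manifest
  mk <- function(study_mean, blank_mean) {
    values <- cbind(matrix(study_mean, 1, 6), matrix(100, 1, 4),
                    matrix(blank_mean, 1, 2))
    colnames(values) <- manifest$sample_id
    feature_table(values, data.frame(feature_id = "X", rt = 1, mz = 900))
  }
  # study 100 vs blank 90 at ratio 5: 100 < 450 -> removed
  expect_equal(filter_blank(mk(100, 90), manifest)$removed, "X")
  # study 500 vs blank 90: 500 >= 450 -> retained
  expect_equal(length(filter_blank(mk(500, 90), manifest)$removed), 0)
  # blank mean 0 -> always retained
  expect_equal(length(filter_blank(mk(100, 0), manifest)$removed), 0)
  no_blanks <- manifest[manifest$run_type != "blank", ]
  expect_error(filter_blank(mk(100, 0), no_blanks), "no blank runs")
})

test_that("CV filter is strict at the 50% boundary and conservative on undefined", {
  tab <- feature_table(
    matrix(1, 3, 2, dimnames = list(NULL, c("a", "b"))),
    data.frame(feature_id = c("A", "B", "C"), rt = 1:3, mz = 1:3))
  cvr <- data.frame(feature_id = c("A", "B", "C"),
                    intra_cv = c(60, 50, NA), inter_cv = c(60, 50, NA),
                    cv_max = c(60, 50, NA))
  res <- filter_cv(tab, cvr, max_cv = 50)
  expect_setequal(res$removed, c("A", "C"))   # 60 removed, NA removed
  expect_equal(res$table$features$feature_id, "B")  # exactly 50 retained
  expect_error(filter_cv(tab, cvr[1:2, ]), "cover")
})

test_that("S/N filter is strict at 100 and keeps infinite S/N", {
  tab <- feature_table(
    matrix(1, 3, 2, dimnames = list(NULL, c("a", "b"))),
    data.frame(feature_id = c("A", "B", "C"), rt = 1:3, mz = 1:3,
               sn = c(99, 100, Inf)))
  res <- filter_sn(tab, min_sn = 100)
  expect_equal(res$removed, "A")
  expect_setequal(res$table$features$feature_id, c("B", "C"))
})

test_that("satellite rules remove isotopes and adducts by hand-checkable geometry", {
  samples <- c("s1", "s2", "s3")
  mk <- function(feats, values) {
    colnames(values) <- samples
    feature_table(values, feats)
  }
  # isotope pair: (5.00, 1000.00) intense, (5.00, 1001.0033) weaker
  tab <- mk(data.frame(feature_id = c("P", "I"),
                       rt = c(5, 5), mz = c(1000, 1001.0033)),
            rbind(c(1000, 1100, 900), c(400, 440, 360)))
  expect_equal(filter_satellites(tab)$removed, "I")
  expect_equal(unname(filter_satellites(tab)$reason["I"]), "isotope")
  # isolated feature is retained
  iso <- mk(data.frame(feature_id = "L", rt = 3, mz = 1500),
            matrix(c(10, 11, 12), 1))
  expect_equal(length(filter_satellites(iso)$removed), 0)
  # formate adduct pair, smaller one removed
  tab2 <- mk(data.frame(feature_id = c("P", "A"),
                        rt = c(5, 5), mz = c(1000, 1046.00548)),
             rbind(c(1000, 1100, 900), c(300, 330, 280)))
  expect_equal(unname(filter_satellites(tab2)$reason["A"]), "adduct")
  # co-eluting, correlated, lower-m/z, weaker -> in-source fragment
  tab3 <- mk(data.frame(feature_id = c("P", "F"),
                        rt = c(5, 5), mz = c(1200, 900)),
             rbind(c(1000, 1500, 700), c(210, 310, 150)))
  expect_equal(unname(filter_satellites(tab3)$reason["F"]), "fragment")
  # same pair but RT-separated: retained
  tab4 <- mk(data.frame(feature_id = c("P", "F"),
                        rt = c(5, 6), mz = c(1200, 900)),
             rbind(c(1000, 1500, 700), c(210, 310, 150)))
  expect_equal(length(filter_satellites(tab4)$removed), 0)
})

test_that("the ten-feature cascade fixture yields 10 -> 8 -> 6 -> 5 -> 2 with full accounting", {
  fx <- cascade_fixture()
  res <- run_filter_cascade(fx$table, fx$manifest)
  rep_ <- res$report$report
  expect_equal(rep_$stage, c("blank", "cv", "sn", "satellite"))
  expect_equal(rep_$n_in, c(10, 8, 6, 5))
  expect_equal(rep_$n_out, c(8, 6, 5, 2))
  expect_setequal(res$table$features$feature_id, c("F09", "F10"))
  # per-stage attribution
  aud <- res$report$audit
  expect_setequal(aud$feature_id[aud$stage == "blank"], c("F01", "F02"))
  expect_setequal(aud$feature_id[aud$stage == "cv"], c("F03", "F04"))
  expect_equal(aud$feature_id[aud$stage == "sn"], "F05")
  expect_setequal(aud$feature_id[aud$stage == "satellite"],
                  c("F06", "F07", "F08"))
  expect_equal(sort(unname(aud$reason[aud$stage == "satellite"])),
               c("adduct", "isotope", "isotope"))
  # accounting identity: removals plus survivors equal the initial count
  expect_equal(rep_$n_in[-1], rep_$n_out[-4])
  expect_equal(res$report$n_initial,
               sum(rep_$n_removed) + nrow(res$table$values))
})

test_that("cascade respects explicit stage selection and empty removals", {
  fx <- cascade_fixture()
  only_sn <- run_filter_cascade(fx$table, fx$manifest, stages = "sn")
  expect_equal(only_sn$report$report$stage, "sn")
  expect_equal(only_sn$report$report$n_removed, 1)
  # a table that trips no rule passes unchanged
  clean <- feature_table(
    matrix(c(1000, 1000), 1, dimnames = list(NULL, c("S1", "S2"))),
    data.frame(feature_id = "Z", rt = 1, mz = 900, sn = 500))
  m2 <- data.frame(sample_id = c("S1", "S2"), class = "cancer",
                   run_type = "study", injection_order = 1:2, batch = 1L)
  res <- run_filter_cascade(clean, m2, stages = c("sn", "satellite"))
  expect_equal(sum(res$report$report$n_removed), 0)
  expect_equal(nrow(res$table$values), 1)
})

test_that("on simulated cohorts satellites are purged without touching differential features", {
  sim <- simulate_feature_table(cohort_config(n_features = 300, seed = 3))
  study_ids <- sim$manifest$sample_id[sim$manifest$run_type == "study"]
  raw_int <- rowMeans(sim$table$values[, study_ids], na.rm = TRUE)
  norm <- normalize_to_qc(sim$table, sim$manifest)
  cvr <- qc_cv_report(norm$table, sim$manifest)
  res <- run_filter_cascade(norm$table, sim$manifest, cvr,
                            raw_intensity = raw_int)
  aud <- res$report$audit
  tr <- sim$truth$features
  sat_all <- tr$feature_id[tr$role %in% c("isotope", "adduct", "fragment")]
  pre_sat <- setdiff(rownames(norm$table$values),
                     aud$feature_id[aud$stage != "satellite"])
  sat_in <- intersect(sat_all, pre_sat)
  removed_sat <- aud$feature_id[aud$stage == "satellite"]
  expect_gte(mean(sat_in %in% removed_sat), 0.95)
  diff_ids <- tr$feature_id[tr$differential]
  expect_equal(sum(diff_ids %in% removed_sat), 0)
})
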