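test_that("a response identical to an X column is fit exactly (R2Y ~ 1)", {
  set.seed(1)
  y <- rep(c(0, 1), each = 10)
  # no noise: every column proportional to the response
  x <- cbind(sig = y + 0, sig2 = 3 * y - 1)
  m <- oplsda(x, y, n_ortho = 0, crossval = FALSE)
  expect_gt(m$R2Y, 1 - 1e-8)
  expect_equal(unname(fitted(m)), y, tolerance = 1e-6)
  expect_equal(max(abs(residuals(m))), 0, tolerance = 1e-6)
  expect_error(oplsda(x, rep(0, 20)), "exactly 2 classes")
})

test_that("with no orthogonal component the predictive scores equal NIPALS PLS1", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(10:30, 1); p <- sample(5:50, 1)
    x <- matrix(rnorm(n * p), n, p)
    y01 <- rep(c(0, 1), length.out = n)
    x[, 1] <- x[, 1] + 2 * y01
    sc <- uv_scale(x)
    yc <- y01 - mean(y01)
    m <- oplsda(x, y01, n_ortho = 0, crossval = FALSE)
    oracle <- nipals_pls1(sc$x, yc, 1)
    a <- m$scores / sqrt(sum(m$scores^2))
    b <- oracle$scores[, 1] / sqrt(sum(oracle$scores[, 1]^2))
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-6)
  }
})

test_that("orthogonal components: orthogonality, R2Y monotone, OPLS(1+1) == PLS(2)", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(12:30, 1); p <- sample(8:50, 1)
    x <- matrix(rnorm(n * p), n, p)
    y01 <- rep(c(0, 1), length.out = n)
    x[, 1] <- x[, 1] + 1.5 * y01
    m0 <- oplsda(x, y01, n_ortho = 0, crossval = FALSE)
    m1 <- oplsda(x, y01, n_ortho = 1, crossval = FALSE)
    m2 <- oplsda(x, y01, n_ortho = 2, crossval = FALSE)
    if (m1$n_ortho > 0) {
      orth <- abs(crossprod(m1$scores, m1$ortho_scores))
      expect_lt(max(orth), 1e-8 * sum(m1$scores^2))
    }
    expect_gte(m1$R2Y, m0$R2Y - 1e-10)
    expect_gte(m2$R2Y, m1$R2Y - 1e-10)
    expect_true(m1$R2X >= 0 && m1$R2X <= 1)
    # defining property: filtering one orthogonal component leaves the
    # fitted response of a 2-component PLS unchanged
    sc <- uv_scale(x); yc <- y01 - mean(y01)
    pls2 <- nipals_pls1(sc$x, yc, 2)
    expect_equal(unname(m1$scores * m1$y_loading), unname(pls2$yhat),
                 tolerance = 1e-6)
  }
})

test_that("a planted response-orthogonal direction is captured by the orthogonal component", {
  set.seed(13)
  n <- 40; p <- 30
  y01 <- rep(c(0, 1), each = n / 2)
  yc <- y01 - mean(y01)
  t_o <- rnorm(n); t_o <- resid(lm(t_o ~ yc))       # orthogonal to y
  w_dir <- rnorm(p); o_dir <- rnorm(p)
  x <- 2 * tcrossprod(yc, w_dir) + 6 * tcrossprod(t_o, o_dir) +
    matrix(rnorm(n * p, sd = 0.3), n, p)
  m0 <- oplsda(x, y01, n_ortho = 0, crossval = FALSE)
  m1 <- oplsda(x, y01, n_ortho = 1, crossval = FALSE)
  expect_gt(m1$R2Y, m0$R2Y + 0.02)
})

test_that("prediction is self-consistent, duplicates agree, missing features error", {
  set.seed(21)
  x <- matrix(rnorm(30 * 15), 30, 15,
              dimnames = list(sprintf("s%d", 1:30), sprintf("f%d", 1:15)))
  y <- rep(c("a", "b"), 15)
  x[, 3] <- x[, 3] + 2 * (y == "b")
  m <- oplsda(x, y, n_ortho = 1, crossval = FALSE)
  pr <- predict(m, x)
  expect_equal(pr$t_pred, unname(m$scores), tolerance = 1e-10)
  expect_equal(pr$y_hat, unname(fitted(m)), tolerance = 1e-10)
  dup <- x[c(4, 4), ]
  pd <- predict(m, dup)
  expect_equal(pd[1, ], pd[2, ], ignore_attr = TRUE)
  expect_error(predict(m, x[, -3]), "missing")
  expect_true(all(pr$class %in% c("a", "b")))
})

test_that("held-out samples from separable classes land on the right side", {
  sim <- simulate_feature_table(cohort_config(
    n_features = 400, frac_differential = 0.2, effect_log2fc = 1.5,
    isotope_prob = 0, adduct_prob = 0, fragment_prob = 0, seed = 31))
  st <- study_matrix(sim)
  sp <- make_split(st$classes, 0.8, seed = 3)
  m <- oplsda(st$x[sp$train, ], st$classes[sp$train], n_ortho = 1,
              crossval = FALSE)
  pr <- predict(m, st$x[sp$test, ])
  expect_gte(mean(pr$class == unname(st$classes[sp$test])), 0.9)
})

test_that("cross-validation: Q2 <= R2Y, permuted labels collapse, folds stay stratified", {
  sim <- simulate_feature_table(cohort_config(
    n_features = 500, frac_differential = 0.15, effect_log2fc = 1.2,
    isotope_prob = 0, adduct_prob = 0, fragment_prob = 0, seed = 41))
  st <- study_matrix(sim)
  sc <- uv_scale(st$x)
  y01 <- as.numeric(st$classes == "control")
  cv <- oplsda_crossval(sc$x, y01, n_ortho = 1, k = 7, seed = 5)
  m <- oplsda(st$x, st$classes, n_ortho = 1, k = 7, seed = 5)
  expect_lte(m$Q2cum, m$R2Y)
  expect_gt(cv$q2cum, 0.5)
  # every fold holds both classes
  expect_true(all(vapply(sort(unique(cv$folds)), function(f)
    length(unique(y01[cv$folds == f])) == 2, TRUE)))
  # label permutation: no predictive structure left
  set.seed(6)
  q2p <- replicate(8, oplsda_crossval(sc$x, sample(y01), n_ortho = 1,
                                      k = 7, seed = 99)$q2cum)
  expect_lte(median(q2p), 0.1)
  expect_error(oplsda_crossval(sc$x, y01, k = 1), "at least 2 folds")
})

test_that("top predictive weights are enriched for planted differential features", {
  sim <- simulate_feature_table(cohort_config(
    n_features = 1000, frac_differential = 0.1, effect_log2fc = 1,
    isotope_prob = 0, adduct_prob = 0, fragment_prob = 0, seed = 55))
  st <- study_matrix(sim)
  m <- oplsda(st$x, st$classes, n_ortho = 1, crossval = FALSE)
  w <- abs(coef(m))
  n_diff <- sum(sim$truth$features$differential)
  top <- names(sort(w, decreasing = TRUE))[seq_len(n_diff)]
  diff_ids <- sim$truth$features$feature_id[sim$truth$features$differential]
  enrichment <- mean(top %in% diff_ids) / (n_diff / length(w))
  expect_gte(enrichment, 5)
})

test_that("auto component selection picks a Q2-maximizing count in 0..3", {
  sim <- simulate_feature_table(cohort_config(
    n_features = 200, frac_differential = 0.2, effect_log2fc = 1.2,
    isotope_prob = 0, adduct_prob = 0, fragment_prob = 0, seed = 61))
  st <- study_matrix(sim)
  m <- oplsda(st$x, st$classes, n_ortho = "auto", k = 5, seed = 2)
  expect_true(m$n_ortho %in% 0:3)
  expect_false(is.na(m$Q2cum))
})
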