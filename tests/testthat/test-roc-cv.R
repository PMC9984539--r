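test_that("AUC matches hand-counted concordance on the worked examples", {
  expect_equal(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_curve(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  expect_equal(roc_curve(c(1, 1, 2, 2), c(0, 1, 0, 1))$auc, 0.5)  # ties = 1/2
  set.seed(20)
  null_auc <- roc_curve(rnorm(2000), rep(c(0, 1), 1000))$auc
  expect_lt(abs(null_auc - 0.5), 0.05)
})

test_that("AUC and Youden equal the exhaustive oracles on random small instances", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    y <- integer(n)
    while (length(unique(y)) < 2) y <- rbinom(n, 1, 0.5)
    scores <- round(rnorm(n), 1)       # rounding forces ties
    roc <- roc_curve(scores, y)
    expect_equal(roc$auc, auc_bruteforce(scores, y), tolerance = 1e-12)
    yt <- youden_threshold(roc)
    oracle <- youden_bruteforce(scores, y)
    expect_equal(yt$J, oracle$J, tolerance = 1e-12)
    expect_equal(yt$sensitivity, oracle$sensitivity, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  scores <- rnorm(60)
  y <- rbinom(60, 1, plogis(scores))
  ours <- roc_curve(scores, y)$auc
  ref <- as.numeric(suppressMessages(pROC::auc(y, scores)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("Youden extremes behave: perfect separation J = 1, null J near 0", {
  roc1 <- roc_curve(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))
  expect_equal(youden_threshold(roc1)$J, 1)
  set.seed(23)
  roc0 <- roc_curve(rnorm(4000), rep(c(0, 1), 2000))
  expect_lt(youden_threshold(roc0)$J, 0.12)
})

test_that("the unpaired t test reproduces hand computations and flags degeneracy", {
  out <- compare_groups_t(c(2, 3, 4, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(out$t, 1.224745, tolerance = 1e-6)
  expect_equal(out$df, 4)
  expect_equal(out$p, 0.2878641, tolerance = 1e-6)
  same <- compare_groups_t(c(5, 5, 5, 5), c(1, 1, 0, 0))
  expect_true(same$degenerate)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  sep <- compare_groups_t(c(1, 1, 1, 0, 0, 0) + c(0, 1e-9, -1e-9) / 1e3,
                          c(1, 1, 1, 0, 0, 0))
  expect_lt(sep$p, 0.001)
})

test_that("LOOCV separates a strong planted signal and stays honest under a null", {
  d <- make_panel_data(n_per_group = 20, n_feat = 4, n_inf = 2, d = 3,
                       seed = 30)
  cv <- loocv(d$x, d$y)
  expect_gte(cv$sensitivity, 0.9)
  expect_gte(cv$specificity, 0.9)
  expect_gt(cv$auc, 0.95)

  set.seed(31)
  yshuf <- sample(d$y)
  cv0 <- loocv(d$x, yshuf)
  expect_lt(abs(cv0$accuracy - 0.5), 0.2)
})

test_that("LOOCV metrics come from held-out predictions only (no leakage)", {
  # with permuted labels the held-out accuracy distribution centers at 0.5
  accs <- vapply(1:12, function(s) {
    d <- make_panel_data(n_per_group = 8, n_feat = 5, n_inf = 0, d = 0,
                         seed = 300 + s)
    loocv(d$x, d$y)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("k-fold CV is seed-reproducible and reduces k for small classes", {
  d <- make_panel_data(n_per_group = 15, n_feat = 4, n_inf = 1, d = 2,
                       seed = 33)
  a <- kfold_cv(d$x, d$y, k = 5, seed = 7)
  b <- kfold_cv(d$x, d$y, k = 5, seed = 7)
  expect_identical(a$folds, b$folds)
  expect_identical(a[c("sensitivity", "specificity", "mae")],
                   b[c("sensitivity", "specificity", "mae")])
  c2 <- kfold_cv(d$x, d$y, k = 5, seed = 8)
  expect_false(identical(a$folds, c2$folds))

  y_small <- c(rep(1, 4), rep(0, 26))
  x_small <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "f"))
  expect_warning(res <- kfold_cv(x_small, y_small, k = 10, seed = 1),
                 "reducing folds")
  expect_equal(res$k, 4)
})

test_that("k-fold MAE tracks predictor quality", {
  d <- make_panel_data(n_per_group = 20, n_feat = 1, n_inf = 1, d = 6,
                       seed = 34)
  good <- kfold_cv(d$x, d$y, k = 10, seed = 2)
  expect_lt(good$mae, 0.05)
  d0 <- make_panel_data(n_per_group = 20, n_feat = 3, n_inf = 0, seed = 35)
  flat <- kfold_cv(d0$x, d0$y, k = 10, seed = 2)
  expect_lt(abs(flat$mae - 0.5), 0.15)
})

test_that("LOOCV and 10-fold agree on a well-powered cohort", {
  d <- make_panel_data(n_per_group = 40, n_feat = 5, n_inf = 2, d = 1.5,
                       seed = 36)
  a <- loocv(d$x, d$y)
  b <- kfold_cv(d$x, d$y, k = 10, seed = 3)
  expect_lt(abs(a$sensitivity - b$sensitivity), 0.1)
  expect_lt(abs(a$specificity - b$specificity), 0.1)
  expect_lt(abs(a$auc - b$auc), 0.1)
})

test_that("AIC follows n ln(MAE) + 2 (m + 1) with the degenerate sentinel", {
  expect_equal(aic_model(0.25, m_features = 4, n = 40),
               40 * log(0.25) + 10)
  expect_equal(aic_model(0.25, 4, 40), -45.45177, tolerance = 1e-4)
  # fixed mae, m 3 -> 5 raises AIC by 4
  expect_equal(aic_model(0.3, 5, 40) - aic_model(0.3, 3, 40), 4)
  # halving the mae at fixed m lowers AIC by n ln 2
  expect_equal(aic_model(0.2, 3, 40) - aic_model(0.4, 3, 40), -40 * log(2))
  z <- aic_model(0, 2, 40)
  expect_equal(as.numeric(z), -Inf)
  expect_true(attr(z, "degenerate"))
})
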