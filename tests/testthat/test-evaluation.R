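test_that("the factorial grids honor the design invariants", {
  cpm <- enumerate_models("cpm")
  krr <- enumerate_models("krr")
  mm <- enumerate_models("metamatch")
  expect_true(all(!is.na(cpm$sign)))
  expect_true(all(is.na(krr$sign)))
  expect_true(all(mm$predictor == "baseline_fc"))
  expect_false(anyDuplicated(cpm) > 0)
  expect_error(enumerate_models("svm"), "arg")
})

test_that("pooled split correlations match a hand-computed oracle", {
  set.seed(71)
  X <- matrix(rnorm(8 * 5), 8, 5)
  y <- rnorm(8)
  folds <- rep(1:4, each = 2)
  # mock predictor that returns the first feature: pooled predictions
  # are exactly X[, 1], so r must equal cor(X[, 1], y)
  mock <- function(X_train, y_train, X_test, seed) X_test[, 1]
  expect_equal(run_split(X, y, folds, mock), cor(X[, 1], y))
  # perfect and anti-perfect predictors
  lookup <- function(X_train, y_train, X_test, seed)
    y[match(X_test[, 1], X[, 1])]
  expect_equal(run_split(X, y, folds, lookup), 1)
  anti <- function(X_train, y_train, X_test, seed)
    -y[match(X_test[, 1], X[, 1])]
  expect_equal(run_split(X, y, folds, anti), -1)
  # constant pooled predictions give 0 with a warning
  flat <- function(X_train, y_train, X_test, seed) rep(2, nrow(X_test))
  expect_warning(r0 <- run_split(X, y, folds, flat), "constant")
  expect_equal(r0, 0)
})

test_that("evaluate_model averages per-split correlations deterministically", {
  coh <- tiny_cohort(seed = 72, n_subjects = 16, attrition_fraction = 0)
  xy <- cohort_xy(coh)
  fit <- model_fitter("cpm", sign = "positive")
  one <- evaluate_model(xy$X, xy$y, fit, split_scheme(1, 4, 5))
  expect_equal(one$r_mean, one$r_split[1])
  many_a <- evaluate_model(xy$X, xy$y, fit, split_scheme(4, 4, 5))
  many_b <- evaluate_model(xy$X, xy$y, fit, split_scheme(4, 4, 5))
  expect_identical(many_a, many_b)
  expect_equal(many_a$r_mean, mean(many_a$r_split))
  expect_true(all(abs(many_a$r_split) <= 1))
})

test_that("permutation p-values follow the tie-inclusive counting convention", {
  nulls <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(westfall_young(matrix(nulls, 4, 1), 0.25), 0.5)
  expect_equal(westfall_young(matrix(nulls, 4, 1), 10), 0)
  expect_equal(westfall_young(matrix(nulls, 4, 1), -10), 1)
  expect_equal(westfall_young(matrix(nulls, 4, 1), 0.3), 0.5)  # tie counts
  expect_equal(westfall_young(matrix(nulls, 4, 1), 0.25,
                              estimator = "add_one"), 3 / 5)
})

test_that("max-statistic correction dominates per-model p-values", {
  # hand-enumerated 4-permutation x 2-model example
  nulls <- rbind(c(0.1, 0.5), c(0.2, 0.1), c(0.3, 0.2), c(0.4, 0.0))
  observed <- c(0.25, 0.35)
  # maxima per permutation: 0.5, 0.2, 0.3, 0.4
  expect_equal(westfall_young(nulls, observed), c(3 / 4, 2 / 4))
  # single model: p_fwe reduces to p
  expect_equal(westfall_young(nulls[, 1, drop = FALSE], 0.25), 0.5)
  # p_fwe >= p on random inputs
  set.seed(73)
  for (i in 1:10) {
    nm <- matrix(rnorm(60), 12, 5)
    obs <- rnorm(5)
    p <- vapply(1:5, function(j) mean(nm[, j] >= obs[j]), numeric(1))
    expect_true(all(westfall_young(nm, obs) >= p))
  }
  expect_error(westfall_young(nulls, c(1, 2, 3)), "match")
})

test_that("the batched CPM study equals the generic per-model path", {
  coh <- tiny_cohort(seed = 74, n_subjects = 16, attrition_fraction = 0,
                     effect_r2 = 0)
  tm <- target_matrix(coh)
  ps <- cpm_permutation_study(tm$X, tm$Y, n_perm = 5, n_splits = 3,
                              perm_splits = 2, base_seed = 21)
  expect_equal(dim(ps$null_rmeans), c(5, 8))
  expect_true(all(ps$p_fwe >= ps$p - 1e-12))
  # generic path for two of the eight models
  for (j in c(1, 4)) {
    tgt <- ps$models$target[j]; sg <- ps$models$sign[j]
    fit <- model_fitter("cpm", sign = sg)
    ev <- evaluate_model(tm$X, tm$Y[, tgt], fit, split_scheme(3, 4, 21))
    pt <- permutation_test(tm$X, tm$Y[, tgt], fit, split_scheme(3, 4, 21),
                           n_perm = 5, perm_splits = 2, observed = ev$r_mean)
    expect_equal(ps$observed[j], ev$r_mean, tolerance = 1e-12)
    expect_equal(ps$null_rmeans[, j], pt$null_rmeans, tolerance = 1e-12)
    expect_equal(ps$p[j], pt$p)
  }
})

test_that("in-fold feature selection is load-bearing: a leaky mutant inflates the null", {
  # pure-noise data; the leaky mutant selects features on ALL subjects
  # before cross-validation, the proper path selects within training
  # folds only
  r_proper <- numeric(15)
  r_leaky <- numeric(15)
  for (i in 1:15) {
    set.seed(7400 + i)
    X <- matrix(rnorm(24 * 60), 24, 60)
    y <- rnorm(24)
    sch <- split_scheme(2, 4, base_seed = i)
    r_proper[i] <- evaluate_model(X, y,
                                  model_fitter("cpm", sign = "positive",
                                               alpha = 0.2), sch)$r_mean
    leaky_edges <- cpm_select_features(X, y, "positive", alpha = 0.2)
    leaky_fit <- function(X_train, y_train, X_test, seed) {
      s_tr <- cpm_summary_score(X_train, leaky_edges)
      s_te <- cpm_summary_score(X_test, leaky_edges)
      if (length(leaky_edges) == 0 || sd(s_tr) == 0)
        return(rep(mean(y_train), nrow(X_test)))
      b <- cov(s_tr, y_train) / var(s_tr)
      mean(y_train) - b * mean(s_tr) + b * s_te
    }
    r_leaky[i] <- suppressWarnings(evaluate_model(X, y, leaky_fit, sch)$r_mean)
  }
  expect_gt(mean(r_leaky), mean(r_proper) + 0.3)
  expect_lt(mean(r_proper), 0.1)   # proper nulls are near or below zero
  expect_gt(mean(r_leaky), 0.3)
})

test_that("null r_mean stays below the signal range (with the CV-selection negative bias)", {
  # out-of-fold correlation under the null is biased toward negative
  # values (training-fold selection anti-generalises), so the relevant
  # property is that the upper tail stays small
  rm <- vapply(1:20, function(i) {
    coh <- generate_cohort(cohort_config(n_subjects = 48, n_regions = 6,
                                         n_timepoints = 60, effect_r2 = 0,
                                         n_causal_edges = 0,
                                         attrition_fraction = 0,
                                         seed = 7500 + i))
    xy <- cohort_xy(coh)
    evaluate_model(xy$X, xy$y, model_fitter("cpm", sign = "positive"),
                   split_scheme(5, 4, i))$r_mean
  }, numeric(1))
  expect_gte(mean(rm < 0.2), 0.9)
  expect_true(all(rm > -0.6))
  expect_lt(mean(rm), 0.05)
})
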