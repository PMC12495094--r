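test_that("the similarity kernel matches per-pair correlations of subjects", {
  set.seed(41)
  A <- matrix(rnorm(6 * 10), 6, 10)
  K <- build_kernel(A)
  expect_equal(unname(diag(K)), rep(1, 6))
  expect_equal(K, t(K))
  for (i in 1:6) for (j in 1:6) {
    if (i != j)
      expect_equal(K[i, j], cor(A[i, ], A[j, ]), tolerance = 1e-12)
  }
  # proportional feature vectors have similarity 1
  B <- rbind(A[1, ], 3 * A[1, ] )
  expect_equal(build_kernel(B)[1, 2], 1, tolerance = 1e-12)
  # constant subject is named in the error
  A2 <- A; A2[3, ] <- 7; rownames(A2) <- paste0("sub", 1:6)
  expect_error(build_kernel(A2), "sub3")
})

test_that("fitting requires a usable target and enough subjects", {
  set.seed(42)
  X <- matrix(rnorm(12 * 10), 12, 10)
  expect_error(krr_fit(X, rep(1, 12)), "constant")
  expect_error(krr_fit(X[1:6, ], rnorm(6)), "at least 8")
})

test_that("a singleton grid is chosen outright and predictions match a dense solve", {
  set.seed(43)
  X <- matrix(rnorm(12 * 10), 12, 10)
  y <- rnorm(12)
  lam <- 0.37
  m <- krr_fit(X, y, lambda_grid = lam, seed = 5)
  expect_equal(m$lambda, lam)
  X_test <- matrix(rnorm(4 * 10), 4, 10)
  # independent dense-solver oracle
  K <- cor(t(X))
  alpha <- solve(K + lam * diag(12), y - mean(y))
  pred_oracle <- drop(cor(t(X_test), t(X)) %*% alpha) + mean(y)
  expect_equal(predict(m, X_test), pred_oracle, tolerance = 1e-8)
})

test_that("ridge limits behave: interpolation at small lambda, mean at large", {
  set.seed(44)
  X <- matrix(rnorm(10 * 40), 10, 40)
  y <- rnorm(10)
  m_small <- krr_fit(X, y, lambda_grid = 1e-8, seed = 1)
  expect_equal(predict(m_small, X[3, , drop = FALSE]), y[3], tolerance = 1e-5,
               ignore_attr = TRUE)
  m_big <- krr_fit(X, y, lambda_grid = 1e12, seed = 1)
  expect_equal(unname(predict(m_big, X)), rep(mean(y), 10), tolerance = 1e-3)
})

test_that("test-prediction variance shrinks monotonically in lambda", {
  set.seed(45)
  X <- matrix(rnorm(15 * 20), 15, 20)
  y <- rnorm(15)
  X_test <- matrix(rnorm(8 * 20), 8, 20)
  v <- vapply(c(0.01, 0.1, 1, 10, 100, 1000), function(l)
    var(predict(krr_fit(X, y, lambda_grid = l, seed = 1), X_test)),
    numeric(1))
  expect_true(all(diff(v) <= 1e-12))
})

test_that("training-subject order does not affect predictions", {
  set.seed(46)
  X <- matrix(rnorm(12 * 15), 12, 15)
  y <- rnorm(12)
  X_test <- matrix(rnorm(3 * 15), 3, 15)
  perm <- sample(12)
  m1 <- krr_fit(X, y, lambda_grid = 0.5, seed = 1)
  m2 <- krr_fit(X[perm, ], y[perm], lambda_grid = 0.5, seed = 1)
  expect_equal(predict(m1, X_test), predict(m2, X_test), tolerance = 1e-9)
})

test_that("inner CV selects lambda deterministically given the seed", {
  coh <- tiny_cohort(seed = 47, n_subjects = 24, attrition_fraction = 0)
  xy <- cohort_xy(coh)
  m1 <- suppressWarnings(krr_fit(xy$X, xy$y, seed = 9))
  m2 <- suppressWarnings(krr_fit(xy$X, xy$y, seed = 9))
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(m1$dual_weights, m2$dual_weights)
  expect_true(m1$lambda %in% m1$lambda_grid)
  # with fewer edges than subjects the kernel is rank deficient, so
  # lambda = 0 is skipped with a warning
  expect_warning(krr_fit(xy$X[, 1:10], xy$y, lambda_grid = c(0, 1), seed = 9),
                 "skipped")
})

test_that("the batched permutation path equals the generic path", {
  coh <- tiny_cohort(seed = 48, n_subjects = 16, n_regions = 6,
                     attrition_fraction = 0, effect_r2 = 0)
  xy <- cohort_xy(coh)
  grid <- c(0.1, 1, 10)
  sch <- split_scheme(3, 4, base_seed = 13)
  ev <- suppressWarnings(
    evaluate_model(xy$X, xy$y, model_fitter("krr", lambda_grid = grid), sch))
  pt <- suppressWarnings(
    permutation_test(xy$X, xy$y, model_fitter("krr", lambda_grid = grid),
                     sch, n_perm = 4, perm_splits = 2, observed = ev$r_mean))
  ks <- krr_permutation_study(xy$X, xy$y, lambda_grid = grid, n_perm = 4,
                              n_splits = 3, perm_splits = 2, base_seed = 13)
  expect_equal(ks$observed, ev$r_mean, tolerance = 1e-10)
  expect_equal(ks$null_rmeans, pt$null_rmeans, tolerance = 1e-10)
  expect_equal(ks$p, pt$p)
})
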