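# Repeated-split 4-fold cross-validation, r_mean scoring, seeded
# permutation nulls, and Westfall-Young max-statistic familywise-error
# correction over the factorial model grid.

#' Enumerate the factorial model grid for one algorithm
#'
#' CPM crosses outcome measure (2) x time point (2) x predictor (2) x
#' feature-selection sign (2) = 16 models; KRR drops the sign factor
#' (8 models); meta-matching additionally applies to baseline FC only
#' (4 models), since its bank is trained on single-visit scans.
#'
#' @param algorithm `"cpm"`, `"krr"`, or `"metamatch"`.
#' @return Data frame with columns `algorithm`, `measure`, `timepoint`,
#'   `predictor`, `sign` (`NA` except for CPM).
#' @examples
#' nrow(enumerate_models("cpm"))  # 16
#' @export
enumerate_models <- function(algorithm = c("cpm", "krr", "metamatch")) {
  algorithm <- match.arg(algorithm)
  measures <- c("functioning", "symptoms")
  timepoints <- c(6, 12)
  predictors <- switch(algorithm,
                       metamatch = "baseline_fc",
                       c("baseline_fc", "delta_fc"))
  signs <- if (algorithm == "cpm") c("positive", "negative") else NA_character_
  grid <- expand.grid(sign = signs, predictor = predictors,
                      timepoint = timepoints, measure = measures,
                      stringsAsFactors = FALSE)
  data.frame(algorithm = algorithm,
             grid[, c("measure", "timepoint", "predictor", "sign")],
             row.names = NULL)
}

#' Construct a repeated-split cross-validation scheme
#'
#' @param n_splits Number of repeated random fold allocations
#'   (main-analysis convention: 100).
#' @param n_folds Folds per split (default 4).
#' @param base_seed Integer base seed; split `s` of permutation `k`
#'   derives its fold allocation from a hash of `(base_seed, k, s)`,
#'   making runs reproducible and parallelisable.
#' @return List of class `split_scheme`.
#' @export
split_scheme <- function(n_splits = 100L, n_folds = 4L, base_seed = 1L) {
  stopifnot(n_splits >= 1, n_folds >= 2)
  structure(list(n_splits = as.integer(n_splits),
                 n_folds = as.integer(n_folds),
                 base_seed = as.integer(base_seed)),
            class = "split_scheme")
}

#' Build a fit/predict closure for one algorithm
#'
#' Returns a function `f(X_train, y_train, X_test, seed)` wrapping the
#' corresponding module, with all model-level randomness (only KRR's
#' inner fold allocation) driven by the passed seed. Every data-driven
#' choice (feature selection, hyperparameter tuning) happens inside the
#' closure, i.e. strictly within training folds.
#'
#' @param algorithm `"cpm"`, `"krr"`, or `"metamatch"`.
#' @param sign CPM feature-selection sign.
#' @param alpha CPM selection threshold.
#' @param lambda_grid Penalty grid for KRR / the meta-matching KRR head.
#' @param bank Trained [train_proxy_bank()] (meta-matching only).
#' @return Function of `(X_train, y_train, X_test, seed)`.
#' @export
model_fitter <- function(algorithm = c("cpm", "krr", "metamatch"),
                         sign = "positive", alpha = 0.05,
                         lambda_grid = krr_lambda_grid(), bank = NULL) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    cpm = function(X_train, y_train, X_test, seed = 1L) {
      predict(cpm_fit(X_train, y_train, sign = sign, alpha = alpha), X_test)
    },
    krr = function(X_train, y_train, X_test, seed = 1L) {
      predict(krr_fit(X_train, y_train, lambda_grid = lambda_grid, seed = seed),
              X_test)
    },
    metamatch = {
      if (is.null(bank)) stop("meta-matching requires a trained proxy bank")
      function(X_train, y_train, X_test, seed = 1L) {
        metamatch_fit_predict(bank, X_train, y_train, X_test,
                              lambda_grid = lambda_grid, seed = seed)
      }
    })
}

#' Score one cross-validation split
#'
#' Rotates each fold out as the test set, collects the out-of-fold
#' predictions for every subject, and returns the single Pearson
#' correlation between the pooled predictions and the observed targets.
#' Constant pooled predictions (an undefined correlation) yield 0 with
#' a warning.
#'
#' @param X Subjects-by-edges feature matrix.
#' @param y Observed targets.
#' @param fold_assignment Integer fold label per subject.
#' @param fit_fun A [model_fitter()] closure.
#' @param seed Base seed for model-level randomness (hashed per fold).
#' @return The split's predicted-observed correlation.
#' @export
run_split <- function(X, y, fold_assignment, fit_fun, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, length(fold_assignment) == n)
  pred <- rep(NA_real_, n)
  for (f in sort(unique(fold_assignment))) {
    te <- fold_assignment == f
    pred[te] <- fit_fun(X[!te, , drop = FALSE], y[!te],
                        X[te, , drop = FALSE], seed = mix_seed(seed, f))
  }
  safe_cor(pred, y, fallback = 0)
}

#' Evaluate a model over repeated random splits
#'
#' Runs [run_split()] for `n_splits` independent random fold
#' allocations and summarises performance as `r_mean`, the arithmetic
#' mean of the per-split correlations.
#'
#' @inheritParams run_split
#' @param scheme A [split_scheme()].
#' @param perm_index Permutation stream index (0 for the observed data;
#'   permutation k of a null ensemble uses k).
#' @return List with `r_split` (per-split correlations) and `r_mean`.
#' @export
evaluate_model <- function(X, y, fit_fun, scheme = split_scheme(),
                           perm_index = 0L) {
  n <- nrow(as.matrix(X))
  if (n < 2 * scheme$n_folds)
    stop("need at least ", 2 * scheme$n_folds, " subjects")
  if (stats::sd(y) == 0) stop("target is constant")
  r <- vapply(seq_len(scheme$n_splits), function(s) {
    sd <- mix_seed(scheme$base_seed, perm_index, s)
    folds <- make_folds(n, scheme$n_folds, seed = sd)
    run_split(X, y, folds, fit_fun, seed = sd)
  }, numeric(1))
  list(r_split = r, r_mean = mean(r))
}

#' Permutation test of prediction performance
#'
#' Shuffles the outcomes among subjects with a seeded permutation,
#' reruns the full pipeline (feature selection and hyperparameter
#' tuning included) for each of `n_perm` permutations at a reduced
#' per-permutation split budget, and reports the proportion of null
#' `r_mean` values at least as large as the observed one.
#'
#' @inheritParams evaluate_model
#' @param n_perm Number of permutations (main-analysis convention:
#'   1000).
#' @param perm_splits Splits per permutation (conventional budgets: 100
#'   for CPM, 50 for KRR, 20 for meta-matching).
#' @param observed Observed `r_mean`; computed with `scheme` if `NULL`.
#' @param estimator `"proportion"` counts ties against the observed
#'   value, `p = #(null >= obs) / n_perm`; `"add_one"` uses the
#'   `(b + 1) / (n_perm + 1)` variant.
#' @return List with `observed`, `null_rmeans`, `p`.
#' @export
permutation_test <- function(X, y, fit_fun, scheme = split_scheme(),
                             n_perm = 1000L, perm_splits = scheme$n_splits,
                             observed = NULL,
                             estimator = c("proportion", "add_one")) {
  estimator <- match.arg(estimator)
  if (n_perm < 1) stop("n_perm must be at least 1")
  n <- nrow(as.matrix(X))
  if (is.null(observed))
    observed <- evaluate_model(X, y, fit_fun, scheme)$r_mean
  perm_scheme <- split_scheme(perm_splits, scheme$n_folds, scheme$base_seed)
  null_rmeans <- vapply(seq_len(n_perm), function(k) {
    perm <- with_seed(mix_seed(scheme$base_seed, k), sample.int(n))
    evaluate_model(X, y[perm], fit_fun, perm_scheme, perm_index = k)$r_mean
  }, numeric(1))
  p <- perm_pvalue(null_rmeans, observed, estimator)
  list(observed = observed, null_rmeans = null_rmeans, p = p)
}

perm_pvalue <- function(null, observed, estimator = "proportion") {
  b <- sum(null >= observed)
  if (estimator == "add_one") (b + 1) / (length(null) + 1) else b / length(null)
}

#' Westfall-Young max-statistic familywise-error correction
#'
#' Given a matrix of null `r_mean` values (rows = permutations, columns
#' = models of one algorithm family, all sharing the same permutation
#' indices), the familywise null value at each permutation is the
#' maximum across models; each model's corrected p-value is the
#' proportion of these maxima at least as large as its observed
#' `r_mean`. Guarantees `p_fwe >= p` for every model.
#'
#' @param null_matrix `n_perm` by `n_models` numeric matrix.
#' @param observed Numeric vector of observed `r_mean`, one per model.
#' @param estimator Tie convention, as in [permutation_test()].
#' @return Numeric vector of `p_fwe` values.
#' @examples
#' nulls <- matrix(rnorm(40), 10, 4)
#' westfall_young(nulls, observed = rep(0.2, 4))
#' @export
westfall_young <- function(null_matrix, observed,
                           estimator = c("proportion", "add_one")) {
  estimator <- match.arg(estimator)
  null_matrix <- as.matrix(null_matrix)
  if (ncol(null_matrix) != length(observed))
    stop("null matrix columns must match the observed vector")
  fwe_null <- apply(null_matrix, 1, max)
  vapply(observed, function(o) perm_pvalue(fwe_null, o, estimator), numeric(1))
}

# ---------------------------------------------------------------------------
# Vectorised CPM batch engine. Evaluates, for a shared feature matrix
# and a set of target columns, all (target x sign) CPM models at once,
# reusing one edge-target correlation pass and one summary-score GEMM
# per fold. Produces results identical to the generic
# evaluate_model()/permutation_test() path (asserted in the tests) at a
# fraction of the cost; intended for permutation ensembles.

# r_mean values for all (target x sign) models on one data set.
cpm_batch_rmeans <- function(X, Y, alpha, n_splits, n_folds, base_seed,
                             perm_index, signs = c("positive", "negative")) {
  n <- nrow(X)
  m <- ncol(Y)
  n_models <- m * length(signs)
  target_of_model <- rep(seq_len(m), each = length(signs))
  r_split <- matrix(NA_real_, n_splits, n_models)
  for (s in seq_len(n_splits)) {
    sd_s <- mix_seed(base_seed, perm_index, s)
    folds <- make_folds(n, n_folds, seed = sd_s)
    pred <- matrix(NA_real_, n, n_models)
    for (f in seq_len(n_folds)) {
      te <- folds == f
      X_tr <- X[!te, , drop = FALSE]
      n_tr <- nrow(X_tr)
      R <- suppressWarnings(stats::cor(X_tr, Y[!te, , drop = FALSE]))
      P <- cor_pvalue(R, n_tr)
      col <- 0L
      sel <- matrix(FALSE, ncol(X), n_models)
      for (t in seq_len(m)) for (sg in signs) {
        col <- col + 1L
        keep <- !is.na(R[, t]) & P[, t] < alpha &
          (if (sg == "positive") R[, t] > 0 else R[, t] < 0)
        sel[keep, col] <- TRUE
      }
      S_tr <- X_tr %*% sel
      S_te <- X[te, , drop = FALSE] %*% sel
      col <- 0L
      for (t in seq_len(m)) for (sg in signs) {
        col <- col + 1L
        y_tr <- Y[!te, t]
        s_tr <- S_tr[, col]
        if (!any(sel[, col]) || stats::sd(s_tr) == 0) {
          pred[te, col] <- mean(y_tr)
        } else {
          slope <- stats::cov(s_tr, y_tr) / stats::var(s_tr)
          pred[te, col] <- mean(y_tr) - slope * mean(s_tr) + slope * S_te[, col]
        }
      }
    }
    for (col in seq_len(n_models))
      r_split[s, col] <- safe_cor(pred[, col], Y[, target_of_model[col]],
                                  fallback = 0, warn = FALSE)
  }
  r_split
}

#' Batched CPM permutation study over a grid of targets and signs
#'
#' Runs the CPM pipeline for every (target column x selection sign)
#' model on a shared feature matrix: observed `r_mean` at the full
#' split budget, a permutation null ensemble at the per-permutation
#' budget, per-model permutation p-values, and Westfall-Young corrected
#' p-values across the grid. Identical in output to calling
#' [evaluate_model()], [permutation_test()] and [westfall_young()]
#' per model with the same seeds, but shares the per-fold correlation
#' pass across models.
#'
#' @param X Subjects-by-edges feature matrix.
#' @param Y Subjects-by-targets matrix of outcome targets (one column
#'   per measure/timepoint combination).
#' @param alpha CPM selection threshold.
#' @param n_perm Number of permutations.
#' @param n_splits Splits for the observed statistic.
#' @param perm_splits Splits per permutation.
#' @param n_folds Folds per split.
#' @param base_seed Base seed shared with the generic path.
#' @param signs Selection signs to cross with the targets.
#' @param estimator Tie convention, as in [permutation_test()].
#' @return List with `models` (data frame of target/sign), `observed`,
#'   `observed_splits` (`n_splits` x models), `null_rmeans` (`n_perm` x
#'   models), `p`, `p_fwe`.
#' @export
cpm_permutation_study <- function(X, Y, alpha = 0.05, n_perm = 1000L,
                                  n_splits = 100L, perm_splits = 100L,
                                  n_folds = 4L, base_seed = 1L,
                                  signs = c("positive", "negative"),
                                  estimator = c("proportion", "add_one")) {
  estimator <- match.arg(estimator)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(nrow(Y) == n)
  if (n < 2 * n_folds) stop("need at least ", 2 * n_folds, " subjects")
  if (any(apply(Y, 2, stats::sd) == 0)) stop("a target column is constant")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("target", seq_len(ncol(Y)))
  models <- expand.grid(sign = signs, target = colnames(Y),
                        stringsAsFactors = FALSE)[, c("target", "sign")]
  models <- models[order(match(models$target, colnames(Y))), ]
  rownames(models) <- NULL

  observed_splits <- cpm_batch_rmeans(X, Y, alpha, n_splits, n_folds,
                                      base_seed, perm_index = 0L,
                                      signs = signs)
  observed <- colMeans(observed_splits)
  null_rmeans <- matrix(NA_real_, n_perm, nrow(models))
  for (k in seq_len(n_perm)) {
    perm <- with_seed(mix_seed(base_seed, k), sample.int(n))
    null_rmeans[k, ] <- colMeans(
      cpm_batch_rmeans(X, Y[perm, , drop = FALSE], alpha, perm_splits,
                       n_folds, base_seed, perm_index = k, signs = signs))
  }
  p <- vapply(seq_len(nrow(models)), function(j)
    perm_pvalue(null_rmeans[, j], observed[j], estimator), numeric(1))
  p_fwe <- westfall_young(null_rmeans, observed, estimator)
  list(models = models, observed = observed,
       observed_splits = observed_splits, null_rmeans = null_rmeans,
       p = p, p_fwe = p_fwe)
}
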