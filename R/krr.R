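# Kernel ridge regression on a between-subject FC-similarity kernel.
# Each test outcome is a regularised weighted mean of training
# outcomes; the l2 penalty is tuned by an inner 4-fold CV loop.

#' Default l2-regularisation grid
#'
#' Sixteen logarithmically spaced values from 1e-3 to 1e4 plus 0,
#' in ascending order. Ties in the inner-CV criterion are broken toward
#' the first (smallest) grid value, so the ordering is part of the
#' contract.
#'
#' @return Numeric vector of candidate lambda values.
#' @export
krr_lambda_grid <- function() {
  c(0, 10^seq(-3, 4, length.out = 16))
}

row_sds <- function(M) {
  n <- ncol(M)
  mu <- rowMeans(M)
  sqrt(pmax(rowSums(M^2) - n * mu^2, 0) / (n - 1))
}

#' Between-subject similarity kernel
#'
#' Entry (i, j) is the Pearson correlation between subject i's and
#' subject j's FC feature vectors; with `B = A` the result is symmetric
#' with unit diagonal. A subject with a constant feature vector has no
#' defined similarity and is a hard error naming the subject.
#'
#' @param A,B Numeric matrices, subjects by edges, sharing one edge
#'   ordering (>= 2 edges).
#' @return `nrow(A)` by `nrow(B)` similarity matrix.
#' @export
build_kernel <- function(A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  same <- identical(A, B)
  if (ncol(A) != ncol(B)) stop("A and B must share the same edge ordering")
  if (ncol(A) < 2) stop("similarity kernel requires at least 2 edges")
  check_rows <- function(M, label) {
    sds <- row_sds(M)
    if (any(sds == 0)) {
      who <- rownames(M)[sds == 0]
      if (is.null(who)) who <- which(sds == 0)
      stop("constant feature vector for ", label, " subject(s): ",
           paste(who, collapse = ", "))
    }
  }
  check_rows(A, "row"); if (!same) check_rows(B, "column")
  K <- stats::cor(t(A), t(B))
  if (same) {
    K <- (K + t(K)) / 2
    diag(K) <- 1
  }
  K
}

# Fast pooled Pearson correlation for short vectors (no NA handling).
fast_cor <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  vx <- sum(x^2) - sx^2 / n
  vy <- sum(y^2) - sy^2 / n
  if (vx <= 0 || vy <= 0) return(NA_real_)
  (sum(x * y) - sx * sy / n) / sqrt(vx * vy)
}

# Hyperparameter selection and dual solve on a precomputed training
# kernel. Returns lambda, dual weights, training mean, and the
# per-candidate mean inner-fold correlation. The inner fold allocation
# (the only randomness) is seed-controlled.
krr_core <- function(K, y, lambda_grid, inner_folds = 4L, seed = 1L,
                     warn = TRUE) {
  n <- length(y)
  n_lambda <- length(lambda_grid)
  tol <- 1e-10

  inner_score <- rep(NA_real_, n_lambda)
  if (n_lambda > 1) {
    fold <- make_folds(n, inner_folds, seed = seed)
    sum_r <- rep(0, n_lambda)
    cnt_r <- rep(0L, n_lambda)
    for (f in seq_len(inner_folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      y_tr <- y[tr]
      mu <- mean(y_tr)
      eig <- eigen(K[tr, tr, drop = FALSE], symmetric = TRUE)
      z <- drop(crossprod(eig$vectors, y_tr - mu))
      KU <- K[te, tr, drop = FALSE] %*% eig$vectors
      scale_ref <- max(abs(eig$values), 1)
      ok <- vapply(lambda_grid, function(l)
        min(eig$values + l) >= tol * scale_ref, logical(1))
      if (!any(ok)) next
      # predictions for every usable lambda in one matrix product
      D <- outer(eig$values, lambda_grid[ok], `+`)
      P <- KU %*% (z / D)                       # n_te x n_ok
      y_te <- y[te] - mean(y[te])
      n_te <- length(te)
      p_mu <- colMeans(P)
      vx <- colSums(P^2) - n_te * p_mu^2
      vy <- sum(y_te^2)
      cov_xy <- drop(crossprod(P, y_te))
      r <- ifelse(vx > 0 & vy > 0, cov_xy / sqrt(vx * vy), NA_real_)
      good <- !is.na(r)
      idx <- which(ok)[good]
      sum_r[idx] <- sum_r[idx] + r[good]
      cnt_r[idx] <- cnt_r[idx] + 1L
    }
    inner_score <- ifelse(cnt_r > 0, sum_r / cnt_r, NA_real_)
  } else {
    inner_score <- 0
  }

  eig <- eigen(K, symmetric = TRUE)
  mu <- mean(y)
  z <- crossprod(eig$vectors, y - mu)
  scale_ref <- max(abs(eig$values), 1)
  solvable <- vapply(lambda_grid, function(l)
    min(eig$values + l) >= tol * scale_ref, logical(1))
  usable <- solvable & !is.na(inner_score)
  if (!any(usable)) stop("no usable lambda in the grid")
  skipped <- which(!usable)
  if (warn && length(skipped))
    warning("skipped singular/unscorable lambda(s): ",
            paste(signif(lambda_grid[skipped], 3), collapse = ", "),
            call. = FALSE)
  score_masked <- ifelse(usable, inner_score, -Inf)
  best <- which.max(score_masked)  # first max: earliest grid entry wins ties
  lambda <- lambda_grid[best]
  alpha <- drop(eig$vectors %*% (z / (eig$values + lambda)))
  list(lambda = lambda, dual_weights = alpha, train_mean = mu,
       inner_score = inner_score)
}

#' Fit kernel ridge regression with inner-CV hyperparameter tuning
#'
#' Builds the training similarity kernel, then for every candidate
#' lambda runs an inner loop of k-fold cross-validation within the
#' training set, scoring each lambda by the mean Pearson correlation
#' between inner-fold predictions and observed outcomes. The lambda
#' maximising that mean is chosen (ties to the earliest grid entry),
#' and the dual weights solve `(K + lambda I) alpha = y - mean(y)` on
#' the full training set; the training mean is stored for re-addition
#' at prediction. A lambda at which the system is singular (typically
#' lambda = 0 with a rank-deficient kernel) is skipped with a warning.
#'
#' @param X Training feature matrix, subjects by edges (>= 8 subjects).
#' @param y Training outcomes, non-constant.
#' @param lambda_grid Candidate penalties, see [krr_lambda_grid()].
#' @param inner_folds Number of inner CV folds (default 4).
#' @param seed Seed for the inner fold allocation (the only randomness).
#' @return An object of class `krr_model` with fields `lambda`,
#'   `lambda_grid`, `dual_weights`, `train_mean`, `X_train`,
#'   `inner_score` (mean inner-fold correlation per candidate).
#' @examples
#' X <- matrix(rnorm(24 * 15), 24, 15)
#' y <- rowSums(X[, 1:3]) + rnorm(24, sd = 0.5)
#' m <- krr_fit(X, y, seed = 7)
#' m$lambda
#' @export
krr_fit <- function(X, y, lambda_grid = krr_lambda_grid(),
                    inner_folds = 4L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("length of y must match rows of X")
  if (n < 2 * inner_folds) stop("need at least ", 2 * inner_folds,
                                " training subjects for ", inner_folds,
                                "-fold inner CV")
  if (stats::sd(y) == 0) stop("target is constant; correlation criterion undefined")
  K <- build_kernel(X)
  core <- krr_core(K, y, lambda_grid, inner_folds, seed)
  structure(c(list(kernel_kind = "pearson_similarity",
                   lambda_grid = lambda_grid, X_train = X),
              core),
            class = "krr_model")
}

#' Predict outcomes from a fitted KRR model
#'
#' Each prediction is the test subject's similarity row against the
#' training subjects, multiplied by the dual weights, plus the training
#' mean -- a regularised weighted mean of the training outcomes.
#'
#' @param object A `krr_model`.
#' @param newdata Feature matrix with the training edge ordering.
#' @param ... Ignored.
#' @return Numeric vector of predicted outcomes.
#' @export
predict.krr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  k_test <- build_kernel(newdata, object$X_train)
  drop(k_test %*% object$dual_weights) + object$train_mean
}

#' @export
print.krr_model <- function(x, ...) {
  cat(sprintf("<krr_model> %d training subjects, lambda = %g\n",
              nrow(x$X_train), x$lambda))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Batched KRR permutation study. The similarity kernel depends only on
# the features, never on the outcomes or the fold allocation, so one
# cohort-level kernel is computed once and subset per training fold;
# the nested tuning loop is otherwise identical (same seeds, same
# tie-breaks) to the generic evaluate_model()/permutation_test() path,
# which the tests assert.

# Pooled split correlation on a precomputed kernel.
krr_split_r <- function(K, y, folds, lambda_grid, inner_folds, split_seed) {
  n <- length(y)
  pred <- rep(NA_real_, n)
  for (f in sort(unique(folds))) {
    te <- folds == f
    tr <- which(!te)
    core <- krr_core(K[tr, tr, drop = FALSE], y[tr], lambda_grid,
                     inner_folds, seed = mix_seed(split_seed, f),
                     warn = FALSE)
    pred[te] <- drop(K[which(te), tr, drop = FALSE] %*% core$dual_weights) +
      core$train_mean
  }
  r <- fast_cor(pred, y)
  if (is.na(r)) 0 else r
}

#' Batched KRR permutation study
#'
#' Observed `r_mean`, permutation null ensemble and p-value for a
#' single KRR model, computed on a cohort-level similarity kernel that
#' is built once and subset per fold (the kernel is a pure function of
#' the features, so this is an exact-equivalence optimisation, not an
#' approximation; hyperparameter tuning still happens inside each
#' training fold).
#'
#' @inheritParams permutation_test
#' @param X Subjects-by-edges feature matrix.
#' @param y Outcome targets.
#' @param lambda_grid Candidate penalties.
#' @param inner_folds Inner CV folds.
#' @param n_splits Splits for the observed statistic.
#' @param perm_splits Splits per permutation.
#' @param n_folds Outer folds per split.
#' @param base_seed Base seed shared with the generic path.
#' @return List with `observed`, `observed_splits`, `null_rmeans`, `p`.
#' @export
krr_permutation_study <- function(X, y, lambda_grid = krr_lambda_grid(),
                                  inner_folds = 4L, n_perm = 1000L,
                                  n_splits = 100L, perm_splits = 50L,
                                  n_folds = 4L, base_seed = 1L,
                                  estimator = c("proportion", "add_one")) {
  estimator <- match.arg(estimator)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2 * n_folds) stop("need at least ", 2 * n_folds, " subjects")
  if (stats::sd(y) == 0) stop("target is constant")
  K <- build_kernel(X)
  eval_splits <- function(y_k, k, splits) {
    vapply(seq_len(splits), function(s) {
      sd_s <- mix_seed(base_seed, k, s)
      folds <- make_folds(n, n_folds, seed = sd_s)
      krr_split_r(K, y_k, folds, lambda_grid, inner_folds, sd_s)
    }, numeric(1))
  }
  observed_splits <- eval_splits(y, 0L, n_splits)
  observed <- mean(observed_splits)
  null_rmeans <- vapply(seq_len(n_perm), function(k) {
    perm <- with_seed(mix_seed(base_seed, k), sample.int(n))
    mean(eval_splits(y[perm], k, perm_splits))
  }, numeric(1))
  list(observed = observed, observed_splits = observed_splits,
       null_rmeans = null_rmeans,
       p = perm_pvalue(null_rmeans, observed, estimator))
}
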