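# Internal helpers: deterministic seeding and fold allocation.

#' Derive a child seed from a base seed and stream indices
#'
#' Mixes a base seed with any number of non-negative integer indices
#' (permutation index, split index, ...) into a single seed below 2^31,
#' so that every randomised stage of a study is reproducible and
#' independently addressable.
#'
#' @param base_seed Integer base seed.
#' @param ... Further non-negative integer indices identifying the stream.
#' @return A single integer seed in `[1, 2147483562]`.
#' @export
mix_seed <- function(base_seed, ...) {
  m <- 2147483563
  parts <- c(base_seed, unlist(list(...)))
  s <- 0
  for (v in parts) {
    s <- (s * 1000003 + (as.double(v) %% m)) %% m
  }
  as.integer(s %% (m - 1L)) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's .Random.seed is restored on exit.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Randomly allocate subjects to cross-validation folds
#'
#' Produces a uniform random partition into `n_folds` folds whose sizes
#' differ by at most one, with no stratification.
#'
#' @param n Number of subjects.
#' @param n_folds Number of folds.
#' @param seed Integer seed controlling the allocation.
#' @return Integer vector of length `n` with fold labels in `1:n_folds`.
#' @examples
#' table(make_folds(10, 4, seed = 1))
#' @export
make_folds <- function(n, n_folds = 4L, seed = 1L) {
  if (n < n_folds) stop("need at least as many subjects as folds")
  with_seed(seed, {
    fold <- rep_len(seq_len(n_folds), n)
    fold[sample.int(n)]
  })
}

# Pearson p-value for correlation r at sample size n via the exact
# t-transform with n - 2 degrees of freedom.
cor_pvalue <- function(r, n) {
  r2 <- pmin(r^2, 1)
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  p
}

# Correlation that returns `fallback` (with an optional warning) when
# either argument is constant, instead of NA plus a cor() warning.
safe_cor <- function(x, y, fallback = 0, warn = TRUE) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    if (warn) warning("correlation undefined for constant input; returning ",
                      fallback, call. = FALSE)
    return(fallback)
  }
  stats::cor(x, y)
}
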