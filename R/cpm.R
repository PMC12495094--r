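# Connectome-based predictive modeling: univariate edge selection by
# correlation sign and p-value, a summed summary score, and a
# one-variable linear model. Entirely deterministic.

#' Select edges univariately correlated with the target
#'
#' For each edge (column of `X`) the Pearson correlation with the
#' training target is computed; an edge is selected when the
#' correlation has the required sign and its two-sided p-value (exact
#' t-transform, `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 df) falls
#' below `alpha`. Positive and negative selections on the same data are
#' disjoint by construction. Edges with zero variance are excluded with
#' a warning (their correlation is undefined).
#'
#' @param X Numeric matrix, subjects by edges (>= 4 subjects).
#' @param y Numeric target vector, non-constant.
#' @param sign `"positive"` (r > 0) or `"negative"` (r < 0).
#' @param alpha Two-sided selection p-value threshold (default .05,
#'   uncorrected; .001 is the conventional stricter alternative).
#' @return Integer vector of selected column indices, with attributes
#'   `r` (their correlations) and `p` (their p-values).
#' @export
cpm_select_features <- function(X, y, sign = c("positive", "negative"),
                                alpha = 0.05) {
  sign <- match.arg(sign)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("feature selection requires at least 4 subjects")
  if (length(y) != n) stop("length of y must match rows of X")
  if (stats::sd(y) == 0) stop("target is constant; selection undefined")
  sds <- matrixStats_colSds(X)
  constant <- sds == 0
  if (any(constant))
    warning(sum(constant), " constant edge column(s) excluded from selection",
            call. = FALSE)
  r <- rep(NA_real_, ncol(X))
  ok <- which(!constant)
  if (length(ok)) r[ok] <- drop(stats::cor(X[, ok, drop = FALSE], y))
  p <- cor_pvalue(r, n)
  keep <- !is.na(r) & p < alpha &
    (if (sign == "positive") r > 0 else r < 0)
  idx <- which(keep)
  attr(idx, "r") <- r[idx]
  attr(idx, "p") <- p[idx]
  idx
}

# colSds without extra dependencies
matrixStats_colSds <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(0, ncol(X)))
  mu <- colMeans(X)
  sqrt(pmax(colSums(X^2) - n * mu^2, 0) / (n - 1))
}

#' Summed FC summary score over selected edges
#'
#' Each subject's FC values are summed across the selected edges,
#' collapsing the selected network to a single scalar predictor. An
#' empty selection yields 0 (the empty-sum convention), which makes the
#' downstream linear fit degenerate to a training-mean predictor.
#'
#' @param X Numeric matrix (subjects by edges) or a single feature row.
#' @param selected_edges Integer vector of edge indices.
#' @return Numeric vector of summary scores, one per subject.
#' @export
cpm_summary_score <- function(X, selected_edges) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (length(selected_edges) == 0) return(rep(0, nrow(X)))
  rowSums(X[, selected_edges, drop = FALSE])
}

#' Fit a connectome-based predictive model
#'
#' Selects edges on the training set ([cpm_select_features()]), sums
#' them into a per-subject summary score ([cpm_summary_score()]), and
#' fits the ordinary least-squares line of the training outcomes on the
#' summary scores. When no edge survives selection, or the summary
#' scores are constant, the model degenerates to predicting the
#' training-mean outcome (slope 0).
#'
#' @inheritParams cpm_select_features
#' @return An object of class `cpm_model` with fields `selected_edges`,
#'   `sign`, `alpha`, `intercept`, `slope`.
#' @examples
#' X <- matrix(rnorm(40 * 10), 40, 10)
#' y <- X[, 3] + rnorm(40, sd = 0.3)
#' m <- cpm_fit(X, y, sign = "positive")
#' cor(predict(m, X), y)
#' @export
cpm_fit <- function(X, y, sign = c("positive", "negative"), alpha = 0.05) {
  sign <- match.arg(sign)
  X <- as.matrix(X)
  edges <- cpm_select_features(X, y, sign = sign, alpha = alpha)
  s <- cpm_summary_score(X, edges)
  if (length(edges) == 0 || stats::sd(s) == 0) {
    intercept <- mean(y)
    slope <- 0
  } else {
    slope <- stats::cov(s, y) / stats::var(s)
    intercept <- mean(y) - slope * mean(s)
  }
  structure(list(selected_edges = as.integer(edges), sign = sign,
                 alpha = alpha, intercept = intercept, slope = slope),
            class = "cpm_model")
}

#' Predict outcomes from a fitted CPM model
#'
#' @param object A `cpm_model`.
#' @param newdata Feature matrix (subjects by edges) with the same edge
#'   ordering as at fit time.
#' @param ... Ignored.
#' @return Numeric vector of predicted outcomes.
#' @export
predict.cpm_model <- function(object, newdata, ...) {
  s <- cpm_summary_score(as.matrix(newdata), object$selected_edges)
  object$intercept + object$slope * s
}

#' @export
print.cpm_model <- function(x, ...) {
  cat(sprintf("<cpm_model> sign = %s, alpha = %g, %d edge(s), y = %.4g %+.4g * score\n",
              x$sign, x$alpha, length(x$selected_edges), x$intercept, x$slope))
  invisible(x)
}

#' Export a selected-edge set as an edge-list table
#'
#' Writes (or returns) the selected edges as a data frame of region
#' pairs with their training correlations, for downstream inspection.
#'
#' @param model A `cpm_model` fitted on vectorised FC features.
#' @param X,y The training data used at fit time (to recover the
#'   per-edge correlations).
#' @param n_regions Region count defining the edge ordering.
#' @param path Optional file path; if given, a tab-delimited file is
#'   written.
#' @return Data frame with columns `i`, `j`, `r` (invisibly if written).
#' @export
cpm_edge_list <- function(model, X, y, n_regions, path = NULL) {
  idx <- model$selected_edges
  ei <- edge_index(n_regions)
  r <- if (length(idx)) drop(stats::cor(as.matrix(X)[, idx, drop = FALSE], y)) else numeric(0)
  out <- data.frame(i = ei[idx, "i"], j = ei[idx, "j"], r = r)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
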