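# Functional-coupling matrices, their longitudinal differences, and the
# fixed-order edge vectorisation used as the feature row by every predictor.

FC_KINDS <- c("baseline_fc", "followup_fc", "delta_fc")

#' Construct a functional-coupling matrix object
#'
#' An `fc_matrix` wraps a symmetric region-by-region coupling matrix
#' (Pearson correlations, or differences of correlations for a
#' longitudinal change matrix) together with ordered region labels and a
#' kind flag.
#'
#' @param values Symmetric numeric matrix.
#' @param labels Character vector of region labels (defaults to rownames
#'   or `"R1"`, `"R2"`, ...).
#' @param kind One of `"baseline_fc"`, `"followup_fc"`, `"delta_fc"`.
#' @return An object of class `fc_matrix`.
#' @export
fc_matrix <- function(values, labels = NULL, kind = "baseline_fc") {
  kind <- match.arg(kind, FC_KINDS)
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("fc_matrix values must be square")
  if (max(abs(values - t(values))) > 1e-8) stop("fc_matrix values must be symmetric")
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- paste0("R", seq_len(n))
  }
  if (length(labels) != n) stop("label length does not match matrix size")
  if (kind == "delta_fc") {
    if (any(abs(values) > 2 + 1e-8)) stop("delta FC entries must lie in [-2, 2]")
  } else {
    if (any(abs(values) > 1 + 1e-8)) stop("FC entries must lie in [-1, 1]")
    if (max(abs(diag(values) - 1)) > 1e-8) stop("FC diagonal must equal 1")
  }
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels, kind = kind),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d regions, kind = %s\n", length(x$labels), x$kind))
  invisible(x)
}

#' Compute a functional-coupling matrix from parcellated time series
#'
#' Entry (i, j) is the Pearson correlation between the mean activity
#' time courses of regions i and j. Requires at least 3 samples and no
#' missing values; a region with zero temporal variance is a hard error
#' (degenerate input, analogous to a failed-quality scan).
#'
#' @param timeseries Numeric matrix, regions in rows, samples in columns.
#' @param kind Kind flag for the result, `"baseline_fc"` or `"followup_fc"`.
#' @return An [fc_matrix] with unit diagonal.
#' @examples
#' ts <- matrix(rnorm(5 * 50), 5, 50)
#' fc <- compute_fc(ts)
#' @export
compute_fc <- function(timeseries, kind = "baseline_fc") {
  kind <- match.arg(kind, c("baseline_fc", "followup_fc"))
  ts <- as.matrix(timeseries)
  if (ncol(ts) < 3) stop("need at least 3 time points per region")
  if (anyNA(ts)) stop("time series contain missing samples")
  labels <- rownames(ts)
  if (is.null(labels)) labels <- paste0("R", seq_len(nrow(ts)))
  sds <- apply(ts, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- labels[which(sds == 0)]
    stop("region(s) with zero temporal variance: ", paste(bad, collapse = ", "))
  }
  vals <- stats::cor(t(ts))
  vals[vals > 1] <- 1
  vals[vals < -1] <- -1
  diag(vals) <- 1
  fc_matrix(vals, labels = labels, kind = kind)
}

#' Longitudinal change in functional coupling
#'
#' Subtracts a subject's baseline FC matrix from their follow-up FC
#' matrix, producing a change (delta) matrix whose entries quantify the
#' per-edge coupling change between the two scans.
#'
#' @param baseline,followup [fc_matrix] objects with identical region
#'   labels; neither may already be a delta matrix.
#' @return An [fc_matrix] of kind `"delta_fc"` with zero diagonal.
#' @export
delta_fc <- function(baseline, followup) {
  stopifnot(inherits(baseline, "fc_matrix"), inherits(followup, "fc_matrix"))
  if (baseline$kind == "delta_fc" || followup$kind == "delta_fc")
    stop("inputs must be non-delta FC matrices")
  if (!identical(baseline$labels, followup$labels))
    stop("region labels differ between baseline and follow-up matrices")
  fc_matrix(followup$values - baseline$values,
            labels = baseline$labels, kind = "delta_fc")
}

#' Edge index of the strict upper triangle, row-major
#'
#' The canonical edge ordering used throughout: (1,2), (1,3), ...,
#' (1,n), (2,3), ..., (n-1,n). Every feature vector in a run uses this
#' one ordering.
#'
#' @param n_regions Number of regions.
#' @return Two-column integer matrix with columns `i`, `j` (`i < j`).
#' @export
edge_index <- function(n_regions) {
  n <- as.integer(n_regions)
  if (n < 2) stop("need at least 2 regions")
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Vectorise a functional-coupling matrix
#'
#' Extracts the strict upper triangle in row-major order, yielding the
#' length n(n-1)/2 feature row used by all prediction algorithms. The
#' ordering matches [edge_index()].
#'
#' @param matrix An [fc_matrix].
#' @return Numeric vector of edge values with attribute `edge_index`.
#' @examples
#' fc <- compute_fc(matrix(rnorm(5 * 30), 5, 30))
#' length(fc_vectorize(fc))  # 5 * 4 / 2 = 10 edges
#' @export
fc_vectorize <- function(matrix) {
  stopifnot(inherits(matrix, "fc_matrix"))
  v <- t(matrix$values)[lower.tri(matrix$values)]
  attr(v, "edge_index") <- edge_index(length(matrix$labels))
  v
}

#' Rebuild a symmetric matrix from its edge vector
#'
#' Inverse of [fc_vectorize()]: places the vector back into the strict
#' upper triangle (row-major) and mirrors it.
#'
#' @param values Numeric edge vector of length n(n-1)/2.
#' @param labels Optional region labels.
#' @param kind Kind flag for the rebuilt matrix.
#' @param diag_value Diagonal value (1 for correlation kinds, 0 for delta).
#' @return An [fc_matrix].
#' @export
fc_devectorize <- function(values, labels = NULL, kind = "baseline_fc",
                           diag_value = if (kind == "delta_fc") 0 else 1) {
  m <- length(values)
  n <- (1 + sqrt(1 + 8 * m)) / 2
  if (abs(n - round(n)) > 1e-9) stop("length is not a valid edge count n(n-1)/2")
  n <- as.integer(round(n))
  out <- matrix(0, n, n)
  out[lower.tri(out)] <- values   # row-major upper triangle via transpose
  out <- t(out)
  out <- out + t(out)
  diag(out) <- diag_value
  fc_matrix(out, labels = labels, kind = kind)
}

#' Read and write FC matrices as square delimited text
#'
#' The on-disk format is tab-delimited with a header row and first
#' column both holding region labels.
#'
#' @param matrix An [fc_matrix].
#' @param path File path.
#' @param kind Kind flag assumed when reading.
#' @return `write_fc` returns `path` invisibly; `read_fc` an [fc_matrix].
#' @export
write_fc <- function(matrix, path) {
  stopifnot(inherits(matrix, "fc_matrix"))
  df <- data.frame(region = matrix$labels, matrix$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fc
#' @export
read_fc <- function(path, kind = "baseline_fc") {
  df <- utils::read.delim(path, check.names = FALSE)
  labels <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  fc_matrix(vals, labels = labels, kind = kind)
}
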